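test_that("statistic catalog counts follow the configuration", {
  cat44 <- statistic_catalog(4, 4, 7)
  counts <- table(cat44$group)
  expect_equal(nrow(cat44), 668L)
  expect_equal(unname(counts[c("linear_cross_position",
                               "magnitude_cross_position",
                               "magnitude_cross_scale",
                               "magnitude_cross_orientation",
                               "linear_phase_cross_scale")]),
               as.integer(c(100, 400, 48, 24, 96)), ignore_attr = TRUE)
  # counts scale predictably with K, O and neighborhood
  for (cfg in list(c(3, 4, 7), c(4, 6, 5), c(2, 2, 3))) {
    K <- cfg[1]; O <- cfg[2]; nb <- cfg[3]
    no <- (nb^2 - 1) / 2 + 1
    cat <- statistic_catalog(K, O, nb)
    tab <- table(cat$group)
    expect_equal(unname(tab["linear_cross_position"]), K * no,
                 ignore_attr = TRUE)
    expect_equal(unname(tab["magnitude_cross_position"]), K * O * no,
                 ignore_attr = TRUE)
    expect_equal(unname(tab["magnitude_cross_scale"]), (K - 1) * O^2,
                 ignore_attr = TRUE)
    expect_equal(unname(tab["magnitude_cross_orientation"]), K * choose(O, 2),
                 ignore_attr = TRUE)
    expect_equal(unname(tab["linear_phase_cross_scale"]), (K - 1) * O^2 * 2,
                 ignore_attr = TRUE)
  }
  expect_error(statistic_catalog(4, 4, 6), "odd")
})

test_that("full statistics: marginals, symmetries and degenerate input", {
  set.seed(11)
  g <- matrix(rnorm(512 * 512), 512)
  gs <- full_statistics(g)
  expect_lt(abs(gs$values[["mar_skew"]]), 0.05)
  expect_equal(gs$values[["mar_kurtosis"]], 3, tolerance = 0.05)

  x <- gray_noise(64, seed = 12)
  fs <- full_statistics(x)
  fr <- full_statistics(x[64:1, 64:1])
  i <- fs$labels$group == "linear_cross_position"
  expect_equal(fs$values[i], fr$values[i], tolerance = 1e-12)

  # zero-lag magnitude covariance equals the variance of the magnitude map
  p <- build_pyramid(x)
  m <- magnitude_responses(p)[[2]][[3]]
  expect_equal(fs$values[["mag_s2_o3_d0.0"]], mean((m - mean(m))^2),
               tolerance = 1e-14)

  d <- full_statistics(matrix(0.4, 64, 64))
  expect_true(d$degenerate)
  expect_true(is.nan(d$values[["mar_skew"]]))
})

test_that("covariance groups are shift-invariant and scale quadratically", {
  x <- gray_noise(64, seed = 13)
  fs <- full_statistics(x)
  sh <- full_statistics(x + 0.17)
  prod_groups <- !(fs$labels$group %in% c("band_mean_magnitude", "marginal"))
  expect_equal(fs$values[prod_groups], sh$values[prod_groups],
               tolerance = 1e-10)
  sc <- full_statistics(0.5 + 2 * (x - 0.5))
  expect_equal(sc$values[prod_groups], 4 * fs$values[prod_groups],
               tolerance = 1e-10)
})

test_that("weighted statistics reduce to unweighted and match a brute-force crop oracle", {
  x <- gray_noise(64, seed = 14)
  p <- build_pyramid(x)
  uni <- observer_statistics(p, matrix(1, 64, 64))
  sub <- observer_subset(full_statistics(x))
  expect_lt(max(abs(uni$values - sub$values)), 1e-10)

  # rectangular weight against explicit product averaging on the full map
  w <- matrix(0, 64, 64)
  w[9:40, 13:52] <- 1
  os <- observer_statistics(p, w)
  q <- p$plow[[1]]
  for (d in list(c(0, 1), c(2, -3))) {
    id <- sprintf("lin_s1_d%d.%d", d[1], d[2])
    expect_lt(abs(os$values[[id]] - brute_weighted_cov(q, w, d[1], d[2])),
              1e-10)
  }
  m <- magnitude_responses(p)[[1]][[2]]
  expect_lt(abs(os$values[["mag_s1_o2_d1.1"]] - brute_weighted_cov(m, w, 1, 1)),
            1e-10)

  expect_error(observer_statistics(p, matrix(0, 64, 64)), "mass")
})

test_that("coefficient of variation follows the (n-1) convention and flags tiny means", {
  x <- gray_noise(32, seed = 15)
  s1 <- full_statistics(x, 2, 2, 3)
  s2 <- s1; s3 <- s1
  s2$values <- s1$values * 2
  s3$values <- s1$values * 3
  cv <- coefficient_of_variation(list(s1, s2, s3))
  # sd/mean keeps the sign of the mean: |cv| = 0.5 for values {v, 2v, 3v}
  expect_equal(abs(cv$cv[!cv$flagged]),
               rep(0.5, sum(!cv$flagged)), tolerance = 1e-12)
  cv0 <- coefficient_of_variation(list(s1, s1, s1))
  expect_true(all(cv0$cv[!cv0$flagged] == 0))
  bad <- full_statistics(x, 2, 3, 3)
  expect_error(coefficient_of_variation(list(s1, bad)), "mismatch")
  expect_error(coefficient_of_variation(list(s1)), "at least 2")
})

test_that("statistic vectors round-trip through the text serialization", {
  x <- gray_noise(32, seed = 16)
  s <- full_statistics(x, 2, 2, 3)
  path <- tempfile(fileext = ".tsv")
  write_statistics(s, path)
  df <- read_statistics(path)
  expect_equal(df$id, rownames(s$labels))
  expect_equal(df$value, unname(s$values), tolerance = 1e-12)
})
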