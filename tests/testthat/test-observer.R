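test_that("pooled responses agree with single-window and full-field statistics", {
  g <- build_windows(64, 24, c(32.5, -24), 0.7)
  ctx <- texpool:::.geom_context(g, 4)
  img <- gray_noise(64, seed = 21)
  R <- pooled_responses(img, g, ctx = ctx)
  expect_equal(dim(R), c(g$n_windows, 668L))
  p <- build_pyramid(img)
  i <- max(1L, g$n_windows %/% 2L)
  os <- observer_statistics(p, matrix(ctx$W[i, ], 64, 64))
  expect_lt(max(abs(R[i, ] - unname(os$values))), 1e-10)

  # a uniform window over the whole field reproduces full-field statistics
  gu <- g
  os_uni <- observer_statistics(p, matrix(1, 64, 64))
  full <- observer_subset(full_statistics(img))
  expect_lt(max(abs(os_uni$values - full$values)), 1e-10)
})

test_that("blank fields give null responses and magnitudes ignore polarity", {
  g <- build_windows(64, 24, c(32.5, -24), 0.7)
  ctx <- texpool:::.geom_context(g, 4)
  Rb <- pooled_responses(matrix(0.5, 64, 64), g, ctx = ctx)
  expect_lt(max(abs(Rb)), 1e-10)

  img <- gray_noise(64, seed = 22)
  R1 <- pooled_responses(img, g, ctx = ctx)
  R2 <- pooled_responses(1 - img, g, ctx = ctx)  # photometric negative
  lab <- statistic_catalog()
  magg <- grepl("^magnitude", lab$group)
  expect_equal(R1[, magg], R2[, magg], tolerance = 1e-10)
})

test_that("rescaling calibration z-scales the ensemble and scales with contrast", {
  ens <- make_calibration_ensemble(8, 64, seed = 3)
  g <- build_windows(64, 24, c(32.5, -24), 0.5)
  ctx <- texpool:::.geom_context(g, 4)
  sds <- calibrate_rescaling(ens, g, min_images = 8, ctx = ctx)
  expect_true(all(sds > 0))
  # after dividing by sds, the ensemble responses have unit sd per statistic
  R <- do.call(rbind, lapply(ens, function(im)
    pooled_responses(0.5 + 0.15 * (im - mean(im)) / sd(im), g, ctx = ctx)))
  expect_equal(apply(sweep(R, 2, sds, "/"), 2, sd), rep(1, 668),
               tolerance = 1e-10, ignore_attr = TRUE)
  # doubling contrast quadruples the product-statistic spread
  sds_lo <- calibrate_rescaling(ens, g, min_images = 8, standardize = FALSE,
                                ctx = ctx)
  ens_hi <- lapply(ens, function(im) 2 * im)
  sds_hi <- calibrate_rescaling(ens_hi, g, min_images = 8,
                                standardize = FALSE, ctx = ctx)
  expect_equal(sds_hi, 4 * sds_lo, tolerance = 1e-8)
  expect_error(calibrate_rescaling(ens[1:3], g, min_images = 8), "at least")
})

test_that("normalization and noise behave as specified", {
  set.seed(30)
  raw <- matrix(rnorm(12 * 668), 12)
  resc <- runif(668, 0.5, 2)
  Rn <- normalize_and_noise(raw, resc, sigma = 0, normalization_on = TRUE)
  expect_equal(sqrt(sum(Rn^2)), 1, tolerance = 1e-12)
  Ri <- normalize_and_noise(raw, resc, sigma = 0, normalization_on = FALSE)
  expect_equal(Ri, sweep(raw, 2, resc, "/"), ignore_attr = TRUE)
  set.seed(7); a <- normalize_and_noise(raw, resc, sigma = 0.1)
  set.seed(7); b <- normalize_and_noise(raw, resc, sigma = 0.1)
  expect_identical(a, b)
  expect_error(normalize_and_noise(matrix(0, 3, 3), NULL, 0, TRUE), "zero-norm")
})

test_that("the AXB rule picks the farther stimulus and breaks ties fairly", {
  A <- matrix(1:6, 2); B <- A + 2; X <- A
  expect_equal(decide_axb(A, X, B), "B")    # X identical to A: B is odd
  expect_equal(decide_axb(B, X, A), "A")
  set.seed(8)
  ties <- replicate(4000, decide_axb(A, A + 1, A))
  expect_lt(abs(mean(ties == "A") - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("SNR calibration round-trips and scales as sigma^-2", {
  set.seed(31)
  resp <- matrix(rnorm(200 * 50, 0, 0.3), 200)
  sig <- calibrate_sigma(resp, 0.5)
  expect_equal(compute_snr(resp, sig), 0.5, tolerance = 1e-10)
  expect_equal(calibrate_sigma(resp, 0.125) / calibrate_sigma(resp, 2), 4,
               tolerance = 1e-12)
})
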