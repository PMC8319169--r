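# synthetic clean-response fixtures: family structure in a small response
# space, so trial machinery can be exercised without the image pipeline
make_fake_responses <- function(nf = 2, ns = 3, M = 40, fam_sd = 1,
                                samp_sd = 0.5, seed = 1) {
  set.seed(seed)
  centers <- lapply(seq_len(nf), function(f) rnorm(M, 0, fam_sd))
  V <- do.call(rbind, lapply(seq_len(nf), function(f)
    t(vapply(seq_len(ns), function(s) centers[[f]] + rnorm(M, 0, samp_sd),
             numeric(M)))))
  index <- expand.grid(sample = seq_len(ns), family = seq_len(nf))[, c("family", "sample")]
  list(V = V, index = index)
}

test_that("trial composition honors the AXB task structure", {
  fx <- make_fake_responses()
  set.seed(2)
  tr <- texpool:::.draw_trials("sample", fx$index, 400)
  # X pixel-identical to exactly one of A, B; A and B same family,
  # different samples
  expect_true(all(tr$x == tr$a | tr$x == tr$b))
  expect_true(all(fx$index$family[tr$a] == fx$index$family[tr$b]))
  expect_true(all(fx$index$sample[tr$a] != fx$index$sample[tr$b]))
  expect_equal(mean(tr$correct_odd == "A"), 0.5, tolerance = 1e-12)

  tr <- texpool:::.draw_trials("family", fx$index, 400)
  expect_true(all(fx$index$family[tr$a] != fx$index$family[tr$b]))
  # X from the matching side's family but never the identical stimulus
  expect_true(all(tr$x != tr$a & tr$x != tr$b))
  xf <- fx$index$family[tr$x]
  matches_a <- xf == fx$index$family[tr$a]
  expect_true(all(matches_a == (tr$correct_odd == "B")))

  expect_error(texpool:::.draw_trials("sample",
                                      data.frame(family = 1:2, sample = c(1, 1)), 10),
               "2 samples")
})

test_that("reduced sampler reproduces direct full-dimensional simulation", {
  fx <- make_fake_responses(seed = 3)
  for (task in c("family", "sample")) for (sigma in c(0.3, 0.8)) {
    pr <- run_discrimination(task, fx$V, fx$index, sigma, 3000, seed = 4)
    pd <- run_discrimination(task, fx$V, fx$index, sigma, 3000, seed = 5,
                             method = "direct")
    se <- sqrt(pr$se^2 + pd$se^2)
    expect_lt(abs(pr$prop_correct - pd$prop_correct), 4 * se + 1e-9)
  }
})

test_that("noiseless and noise-dominated limits are exact", {
  fx <- make_fake_responses(seed = 6)
  expect_equal(run_discrimination("sample", fx$V, fx$index, 0, 500,
                                  seed = 7)$prop_correct, 1)
  p_noise <- run_discrimination("family", fx$V, fx$index, 1e5, 4000,
                                seed = 8)$prop_correct
  expect_lt(abs(p_noise - 0.5), 3 * sqrt(0.25 / 4000))
  # determinism of the full record
  a <- run_discrimination("family", fx$V, fx$index, 0.5, 500, seed = 9)
  b <- run_discrimination("family", fx$V, fx$index, 0.5, 500, seed = 9)
  expect_identical(a, b)
})

test_that("crossover estimation interpolates in log diameter", {
  perf <- data.frame(
    task = rep(c("family", "sample"), each = 3),
    diameter_deg = rep(c(1, 2, 4), 2),
    prop_correct = c(0.4, 0.5, 0.8, 0.8, 0.7, 0.5))
  cd <- crossover_diameter(perf)
  # difference is -0.4, -0.2, +0.3: crossing between 2 and 4 deg
  expect_gt(cd, 2); expect_lt(cd, 4)
  expect_equal(cd, exp(log(2) + 0.4 * log(2)), tolerance = 1e-10)
  none <- data.frame(task = rep(c("family", "sample"), each = 2),
                     diameter_deg = rep(c(1, 2), 2),
                     prop_correct = c(0.9, 0.95, 0.6, 0.65))
  expect_true(is.na(crossover_diameter(none)))
})

test_that("convergence analysis requires replicated samples", {
  fam <- list(list(gray_noise(32, 1)))
  expect_error(convergence_analysis(fam, c(16, 32)), "at least 2 samples")
})

test_that("stimulus-set geometry reproduces the angular size arithmetic", {
  img <- gray_noise(64, seed = 50)
  fams <- list(list(img))
  stim <- build_stimulus_set(fams, widths = c(16, 32, 64), px_per_deg = 80,
                             eccentricities = c(4, 8))
  m <- stim$manifest
  expect_equal(m$diameter_deg[m$ecc_deg == 4],
               c(16, 32, 64) / 80, tolerance = 1e-12)
  # dilated condition: same pixels at half the density, double the size
  expect_equal(m$px_per_deg[m$ecc_deg == 8], rep(40, 3))
  expect_equal(m$diameter_deg[m$ecc_deg == 8], c(16, 32, 64) / 40)
})
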