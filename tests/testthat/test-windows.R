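test_that("pooling windows tile the field exactly and scale with s", {
  for (s in c(0.3, 0.6)) {
    g <- build_windows(128, 40, c(64.5, -48), s)
    expect_lt(max(abs(window_sum(g) - 1)), 1e-12)
  }
  p_small <- build_windows(128, 40, c(64.5, -48), 0.3)$n_windows
  p_large <- build_windows(128, 40, c(64.5, -48), 0.6)$n_windows
  expect_lt(p_large, p_small)
  expect_error(build_windows(128, 40, c(64, 60), 0.5), "inside the field")
})

test_that("window widths grow in proportion to eccentricity", {
  g <- build_windows(128, 40, c(64.5, -48), 0.46)
  # FWHM / eccentricity equals s for every ring
  ratio <- vapply(seq_len(g$n_windows), function(i)
    window_radial_fwhm(g, i) / g$centers$ecc_deg[i], numeric(1))
  expect_equal(ratio, rep(g$s, g$n_windows), tolerance = 1e-12)
  # windows one ring apart have radial widths in the ring spacing ratio
  e <- sort(unique(round(g$centers$ecc_deg, 10)))
  i1 <- which.min(abs(g$centers$ecc_deg - e[1]))
  i2 <- which.min(abs(g$centers$ecc_deg - e[3]))
  expect_equal(window_radial_fwhm(g, i2) / window_radial_fwhm(g, i1),
               g$centers$ecc_deg[i2] / g$centers$ecc_deg[i1],
               tolerance = 1e-10)
})

test_that("geometry is invariant to uniform dilation about fixation", {
  # halving the pixel density doubles all eccentricities; anchored to the
  # field's minimum eccentricity, the window maps are pixel-identical
  g1 <- build_windows(128, 40, c(64.5, -48), 0.5)
  g2 <- build_windows(128, 20, c(64.5, -48), 0.5)
  expect_equal(g1$n_windows, g2$n_windows)
  expect_equal(window_weights(g1), window_weights(g2), tolerance = 1e-10)
  expect_equal(g2$centers$ecc_deg, 2 * g1$centers$ecc_deg, tolerance = 1e-10)
})

test_that("the analytic window integral matches the discrete weight mass", {
  # for a window wholly inside the field, the pixel sum of its weights
  # equals the continuous integral, so full-aperture overlap is 1
  g <- build_windows(256, 32, c(128.5, -64), 0.5)
  W <- window_weights(g)
  inside <- which(vapply(seq_len(g$n_windows), function(i) {
    m <- matrix(W[i, ], 256, 256)
    sum(m[1, ]) + sum(m[256, ]) + sum(m[, 1]) + sum(m[, 256]) == 0
  }, logical(1)))
  expect_gt(length(inside), 0)
  for (i in inside[seq_len(min(3, length(inside)))])
    expect_equal(sum(W[i, ]), g$centers$mass_total[i], tolerance = 0.02)
})

test_that("aspect ratio of radial to circumferential width is about 2", {
  g <- build_windows(128, 40, c(64.5, -48), 0.46)
  i <- which.max(g$centers$ecc_deg > 2)[1]
  radial <- window_radial_fwhm(g, i)
  circum <- g$centers$ecc_deg[i] * g$delta_theta  # angular FWHM = spacing
  expect_gt(radial / circum, 1.5)
  expect_lt(radial / circum, 2.5)
})
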