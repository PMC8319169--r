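test_that("synthesis loss gradients match numerical differentiation", {
  x <- gray_noise(32, seed = 61, sd = 0.2)
  tgt <- full_statistics(x, 2, 3, 3)
  plan <- texpool:::.synth_plan(tgt, 32)
  y <- gray_noise(32, seed = 62, sd = 0.2)
  ev <- texpool:::.synth_eval(y, plan)
  # forward pass equals the reference statistics path exactly
  fs <- full_statistics(y, 2, 3, 3)
  expect_lt(max(abs(ev$stats - unname(fs$values))), 1e-12)
  h <- 1e-6
  set.seed(63)
  idx <- sample(32 * 32, 15)
  num <- vapply(idx, function(i) {
    yp <- y; yp[i] <- yp[i] + h
    ym <- y; ym[i] <- ym[i] - h
    (texpool:::.synth_eval(yp, plan)$loss -
       texpool:::.synth_eval(ym, plan)$loss) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num - ev$grad[idx])) / max(abs(num)), 1e-5)
})

test_that("synthesis from a noise target converges quickly and is seeded", {
  set.seed(64)
  proto <- matrix(rnorm(128 * 128, 0.5, 0.15), 128)
  tgt <- full_statistics(proto)
  img <- synthesize(tgt, 128, seed = 2, max_iters = 10, tol = 1e-2)
  expect_true(attr(img, "converged"))
  expect_true(all(attr(img, "group_err") <= 1e-2))
  img2 <- synthesize(tgt, 128, seed = 2, max_iters = 10, tol = 1e-2)
  expect_identical(unclass(img), unclass(img2))   # bit-identical given seed
  expect_warning(synthesize(tgt, 128, seed = 3, max_iters = 0, tol = 1e-9),
                 "did not reach")
})

test_that("the aperture mask has the specified flat top and cosine ramp", {
  w <- 64
  m <- aperture_mask(w)
  ctr <- (w + 1) / 2
  expect_equal(m[32, 32], 1)
  expect_equal(m[1, 1], 0)   # corner beyond radius w/2
  # value midway through the ramp is 0.5
  r_mid <- (7 / 8 * w / 2 + w / 2) / 2
  val <- 0.5 * (1 + cos(pi * (r_mid - 7 / 8 * w / 2) / (w / 2 - 7 / 8 * w / 2)))
  expect_equal(val, 0.5, tolerance = 1e-12)
  # radially monotone nonincreasing
  d <- seq_len(w) - ctr
  rho <- sqrt(outer(d^2, d^2, "+"))
  ord <- order(as.vector(rho))
  expect_true(all(diff(as.vector(m)[ord]) <= 1e-12))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("crop_and_vignette passes the center and grays the outside", {
  img <- gray_noise(64, seed = 65)
  v <- crop_and_vignette(img, 32, background = 0.5)
  expect_equal(dim(v), c(32L, 32L))
  expect_equal(v[16, 16], img[16 + 16, 16 + 16])
  expect_equal(v[1, 1], 0.5)
  expect_error(crop_and_vignette(img, 100), "exceeds")
})
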