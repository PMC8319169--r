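test_that("pyramid structure and degenerate inputs behave as specified", {
  x <- gray_noise(128, seed = 1)
  p <- build_pyramid(x, 4, 4)
  expect_equal(p$n_scales, 4L)
  expect_equal(length(p$bands), 4L)
  expect_true(all(vapply(p$bands, length, integer(1)) == 4L))
  for (k in 1:4)
    expect_equal(nrow(p$bands[[k]][[1]]), 128 / 2^(k - 1))

  const <- build_pyramid(matrix(0.7, 64, 64), 4, 4)
  expect_equal(mean(const$lowpass), 0.7, tolerance = 1e-12)
  expect_lt(max(vapply(const$bands, function(bk)
    max(vapply(bk, function(b) max(Mod(b)), numeric(1))), numeric(1))), 1e-12)

  expect_error(build_pyramid(matrix(0, 64, 32)), "square")
  expect_error(build_pyramid(matrix(0, 24, 24), 4, 4), "divisible")
  expect_error(build_pyramid(matrix(0, 64, 64), 4, 1), "n_orientations")
})

test_that("transform is a tight frame: reconstruction and Parseval", {
  for (seed in 1:5) {
    x <- matrix(rnorm(96 * 96), 96)
    p <- build_pyramid(x, 4, 4)
    expect_lt(max(abs(reconstruct(p) - x)) / diff(range(x)), 1e-10)
    expect_lt(abs(pyr_energy(p) / sum(x^2) - 1), 1e-10)
  }
})

test_that("reconstruction is linear and zero coefficients give a zero image", {
  x <- gray_noise(64, seed = 2)
  p <- build_pyramid(x, 3, 4)
  z <- p
  z$bands <- lapply(z$bands, function(bk) lapply(bk, function(b) b * 0))
  z$highpass <- z$highpass * 0
  z$lowpass <- z$lowpass * 0
  expect_equal(max(abs(reconstruct(z))), 0)
  a <- p
  a$bands <- lapply(a$bands, function(bk) lapply(bk, function(b) 2.5 * b))
  a$highpass <- 2.5 * a$highpass
  a$lowpass <- 2.5 * a$lowpass
  expect_equal(reconstruct(a), 2.5 * reconstruct(p), tolerance = 1e-12)
})

test_that("magnitude responses are phase-invariant local energy", {
  n <- 128
  # sinusoid at the peak of scale-2, orientation-1 (vertical structure)
  fx <- 2 * pi * 24 / n
  img <- 0.5 + 0.2 * cos(fx * outer(rep(1, n), seq_len(n) - 1))
  p <- build_pyramid(img, 4, 4)
  m <- magnitude_responses(p)[[2]][[1]]
  expect_lt(stats::sd(m) / mean(m), 0.05)   # ~constant envelope

  x <- gray_noise(64, seed = 3, mean = 0)
  m1 <- magnitude_responses(build_pyramid(x, 3, 4))
  m2 <- magnitude_responses(build_pyramid(-x, 3, 4))
  for (k in 1:3) for (o in 1:4)
    expect_equal(m1[[k]][[o]], m2[[k]][[o]], tolerance = 1e-12)
})

test_that("phase doubling doubles the angle, preserves magnitude, upsamples", {
  x <- gray_noise(64, seed = 4)
  p <- build_pyramid(x, 3, 4)
  pd <- phase_doubled_responses(p)
  expect_length(pd, 2L)
  expect_equal(nrow(pd[[1]][[1]]), 64)   # aligned to the finer scale
  # check the pointwise definition before upsampling
  b <- p$bands[[2]][[3]]
  pd_native <- ifelse(Mod(b) > 0, b^2 / Mod(b), 0)
  expect_equal(Mod(pd_native), Mod(b), tolerance = 1e-12)
  expect_equal(Arg(pd_native[2, 3]), ((2 * Arg(b[2, 3]) + pi) %% (2 * pi)) - pi,
               tolerance = 1e-10)
  # real positive coefficient unchanged; purely imaginary flips sign
  expect_equal(ifelse(Mod(2 + 0i) > 0, (2 + 0i)^2 / Mod(2 + 0i), 0), 2 + 0i)
  z <- complex(modulus = 3, argument = pi / 2)
  expect_equal(z^2 / Mod(z), complex(modulus = 3, argument = pi),
               tolerance = 1e-12)
  expect_error(phase_doubled_responses(build_pyramid(gray_noise(32, 1), 1, 4)),
               "2 scales")
})

test_that("rotating the image by 90 degrees permutes orientation energies", {
  set.seed(5)
  x <- matrix(rnorm(64 * 64), 64)
  p1 <- build_pyramid(x, 3, 4)
  p2 <- build_pyramid(t(x)[, 64:1], 3, 4)   # 90-degree rotation
  for (k in 1:3) {
    e1 <- vapply(p1$bands[[k]], function(b) sum(Mod(b)^2), numeric(1))
    e2 <- vapply(p2$bands[[k]], function(b) sum(Mod(b)^2), numeric(1))
    # orientation o maps to o +/- 2 (mod 4) under a quarter turn
    expect_equal(e2, e1[c(3, 4, 1, 2)], tolerance = 0.01 * mean(e1))
  }
})
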