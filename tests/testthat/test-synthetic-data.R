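test_that("prototype generation is deterministic with separable families", {
  p1 <- make_prototypes(4, difficulty = 0.5, seed = 3, size_px = 64)
  p2 <- make_prototypes(4, difficulty = 0.5, seed = 3, size_px = 64)
  expect_identical(p1, p2)
  expect_length(p1, 4L)
  expect_error(make_prototypes(1), ">= 2")
  expect_error(make_prototypes(3, difficulty = 1.2), "difficulty")
  # gray convention
  for (img in p1) {
    expect_equal(mean(img), 0.5, tolerance = 0.02)
    expect_true(all(img >= 0 & img <= 1))
  }
})

test_that("family separation in statistic space shrinks with difficulty", {
  seps <- vapply(c(0, 0.5, 0.9), function(d) {
    pr <- make_prototypes(3, difficulty = d, seed = 5, size_px = 64)
    st <- lapply(pr, function(im) observer_subset(full_statistics(im))$values)
    scale <- sqrt(Reduce(`+`, lapply(st, function(v) v^2)) / 3) + 1e-12
    mean(c(sqrt(sum(((st[[1]] - st[[2]]) / scale)^2)),
           sqrt(sum(((st[[1]] - st[[3]]) / scale)^2)),
           sqrt(sum(((st[[2]] - st[[3]]) / scale)^2))))
  }, numeric(1))
  expect_true(all(diff(seps) < 0))
})

test_that("calibration ensemble is pink, standardized and decorrelated", {
  ens <- make_calibration_ensemble(4, 128, seed = 11)
  for (im in ens) {
    expect_lt(abs(mean(im)), 1e-12)
    expect_equal(mean(im^2), 1, tolerance = 1e-12)
  }
  # radially averaged amplitude slope ~ -1
  im <- ens[[1]]
  A <- Mod(fft(im))
  f <- texpool:::.freq_axis(128)
  r <- sqrt(outer(f^2, f^2, "+"))
  keep <- r > 0.1 & r < 2.5
  bins <- cut(log(r[keep]), 12)
  la <- tapply(log(A[keep]), bins, mean)
  lr <- tapply(log(r[keep]), bins, mean)
  slope <- coef(lm(la ~ lr))[2]
  expect_equal(unname(slope), -1, tolerance = 0.1)
  # distinct seeds are uncorrelated
  ens2 <- make_calibration_ensemble(1, 256, seed = 12)
  ens3 <- make_calibration_ensemble(1, 256, seed = 13)
  expect_lt(abs(cor(as.vector(ens2[[1]]), as.vector(ens3[[1]]))), 0.05)
})

test_that("images round-trip through the supported formats", {
  img <- gray_noise(32, seed = 40)
  img <- pmin(pmax(img, 0), 1)
  for (ext in c(".tif", ".txt")) {
    path <- tempfile(fileext = ext)
    write_image(img, path)
    back <- read_image(path)
    tol <- if (ext == ".tif") 2 / 65535 else 1e-12
    expect_equal(back, img, tolerance = tol)
  }
  path <- tempfile(fileext = ".png")
  write_image(img, path)
  expect_equal(read_image(path), img, tolerance = 2 / 255)
})
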