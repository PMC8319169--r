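## Procedural image generators: prototype textures with controllable
## family-level structure, and a broadband (1/f) calibration ensemble.
## These replace photographic material so the whole pipeline runs with no
## external data.  The three prototype archetypes are chosen to exercise
## different statistic groups: oriented filtered noise (orientation and
## position covariances), fields of compact spots (kurtosis, cross-scale
## magnitude correlations), and edge-rich wave composites (cross-scale
## phase alignment).

# normalize an image to the gray-level convention used throughout:
# mean 0.5, sd 0.15, softly compressed into [0, 1]
.to_gray <- function(z, sd_target = 0.15) {
  z <- (z - mean(z)) / stats::sd(z)
  g <- 0.5 + sd_target * tanh(z / 1.6) * 1.6   # soft clip, keeps sd ~ target
  g
}

.gen_oriented_noise <- function(size, ori, bw, peak, gain) {
  f <- .freq_axis(size)
  fx <- matrix(f, size, size, byrow = TRUE)
  fy <- matrix(f, size, size)
  r <- sqrt(fx^2 + fy^2)
  th <- atan2(fy, fx)
  d <- atan2(sin(2 * (th - ori)), cos(2 * (th - ori))) / 2  # pi-periodic diff
  A <- exp(-d^2 / (2 * bw^2)) * exp(-(log(pmax(r, 1e-6) / peak))^2 / 0.5)
  A[1, 1] <- 0
  z <- Re(.ifft2(A * stats::fft(matrix(stats::rnorm(size^2), size))))
  z <- z / stats::sd(z)
  tanh(gain * z)  # mild rectifying nonlinearity -> higher-order structure
}

.gen_spot_field <- function(size, density, radius, polarity) {
  n_spots <- max(4L, round(density * size^2))
  field <- matrix(0, size, size)
  pos <- cbind(sample.int(size, n_spots, replace = TRUE),
               sample.int(size, n_spots, replace = TRUE))
  amp <- ifelse(stats::runif(n_spots) < polarity, 1, -1)
  field[pos] <- field[pos] + amp
  d <- pmin(0:(size - 1), size - (0:(size - 1)))
  g <- exp(-outer(d^2, d^2, "+") / (2 * radius^2))
  Re(.ifft2(stats::fft(field) * stats::fft(g)))
}

.gen_wave_composite <- function(size, freq, ori, edge_sharp, noise_sd) {
  xy <- seq_len(size)
  gx <- matrix(xy, size, size, byrow = TRUE)
  gy <- matrix(xy, size, size)
  # integer cycle counts keep the waves periodic on the torus
  cyc <- max(2L, round(freq * size))
  # jitter the carrier spatially so the composite is quasi-periodic;
  # strictly periodic gratings make poor (and hard-to-match) textures
  jit <- 0.12 * size * Re(.ifft2(stats::fft(matrix(stats::rnorm(size^2), size)) *
                                   exp(-(.freq_axis(size)^2 %o% rep(1, size) +
                                           rep(1, size) %o% .freq_axis(size)^2) * 40)))
  w1 <- tanh(edge_sharp * sin(2 * pi * cyc * (cos(ori) * gx + sin(ori) * gy) / size +
                                jit))
  ori2 <- ori + pi / 2
  w2 <- tanh(edge_sharp * sin(2 * pi * round(cyc * 1.6) *
                                (cos(ori2) * gx + sin(ori2) * gy) / size - jit))
  w1 + 0.5 * w2 + matrix(stats::rnorm(size^2, 0, noise_sd), size)
}

# archetype parameter sets: each row of deltas displaces one family from
# the shared center; difficulty shrinks the displacement
.prototype_params <- function(family_index) {
  arch <- ((family_index - 1L) %% 3L) + 1L
  variant <- (family_index - 1L) %/% 3L
  list(arch = arch, variant = variant)
}

#' Generate prototype texture images for a set of families
#'
#' Produces `n_families` procedurally generated square textures, cycling
#' through three archetypes (oriented filtered noise, spot fields, wave
#' composites) with per-family parameter displacements.  `difficulty` in
#' `[0, 1]` mixes every prototype toward a shared reference texture:
#' at 0 the families are maximally distinct, and increasing difficulty
#' monotonically shrinks their separation in statistic space (emulating
#' the selection of hard-to-discriminate families).
#'
#' Identical arguments give bit-identical images.  All prototypes follow
#' the package gray-level convention (mean 0.5, sd 0.15).
#'
#' @param n_families number of families (>= 2).
#' @param difficulty in `[0, 1]`.
#' @param seed integer seed.
#' @param size_px image side (default 320).
#' @return list of `n_families` image matrices.
#' @export
make_prototypes <- function(n_families, difficulty = 0.5, seed = 1L,
                            size_px = 320L) {
  if (n_families < 2L) stop("`n_families` must be >= 2")
  if (difficulty < 0 || difficulty > 1) stop("`difficulty` must be in [0, 1]")
  set.seed(as.integer(seed))
  raw <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    p <- .prototype_params(f)
    v <- p$variant
    raw[[f]] <- switch(p$arch,
      .gen_oriented_noise(size_px, ori = (v %% 4) * pi / 4,
                          bw = 0.25 + 0.1 * (v %% 2), peak = 0.5 / (1.5 + 0.5 * v),
                          gain = 1.8),
      .gen_spot_field(size_px, density = 0.002 / (1 + v), radius = 2.2 + 0.8 * v,
                      polarity = 0.7),
      .gen_wave_composite(size_px, freq = 0.045 * (1 + 0.4 * v),
                          ori = pi / 7 + v * pi / 5, edge_sharp = 2.5,
                          noise_sd = 0.35))
    raw[[f]] <- raw[[f]] / stats::sd(raw[[f]])
  }
  # shared reference for the difficulty mix: equal blend of all families
  ref <- Reduce(`+`, raw) / n_families
  ref <- ref / stats::sd(ref)
  lapply(raw, function(z) .to_gray((1 - difficulty) * z + difficulty * ref))
}

#' Generate a broadband (1/f) calibration ensemble
#'
#' Phase-randomized images whose amplitude spectrum falls as 1/f (log-log
#' radial slope -1), mimicking the second-order structure of natural
#' images.  Each image has exactly zero mean and unit variance.  Used to
#' calibrate the per-statistic rescaling of the pooling observer in place
#' of a natural-image database.
#'
#' @param n_images number of images.
#' @param size_px image side.
#' @param seed integer seed.
#' @return list of image matrices.
#' @export
make_calibration_ensemble <- function(n_images, size_px = 256L, seed = 1L) {
  set.seed(as.integer(seed))
  f <- .freq_axis(size_px)
  fx <- matrix(f, size_px, size_px, byrow = TRUE)
  fy <- matrix(f, size_px, size_px)
  r <- sqrt(fx^2 + fy^2)
  A <- 1 / pmax(r, 2 * pi / size_px)
  A[1, 1] <- 0
  lapply(seq_len(n_images), function(i) {
    z <- Re(.ifft2(A * stats::fft(matrix(stats::rnorm(size_px^2), size_px))))
    z <- z - mean(z)
    z / sqrt(mean(z^2))
  })
}
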