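## Complex steerable pyramid, implemented in the frequency domain.
##
## The decomposition splits an image into K scales x O orientations of
## complex (quadrature-pair) bandpass coefficients plus real highpass and
## lowpass residuals.  Filters are polar-separable in the Fourier domain:
## raised-cosine radial profiles on a log-frequency axis and cos^(O-1)
## angular lobes, chosen so that the squared frequency responses tile the
## plane (tight frame; exact reconstruction).  Boundary handling is
## circular, which the frequency-domain construction makes exact.

# cache of frequency-domain masks, keyed by "n.O"
.mask_cache <- new.env(parent = emptyenv())

# frequency grid (radians, [-pi, pi)) for an n x n FFT layout
.freq_axis <- function(n) {
  k <- 0:(n - 1)
  2 * pi * ifelse(k <= n / 2, k, k - n) / n
}

# radial raised-cosine lowpass: 1 below pi/4, 0 above pi/2
.radial_lo <- function(r) {
  out <- matrix(0, nrow(r), ncol(r))
  out[r <= pi / 4] <- 1
  mid <- r > pi / 4 & r < pi / 2
  out[mid] <- cos(pi / 2 * log2(4 * r[mid] / pi))
  out
}

.radial_hi <- function(r) {
  out <- matrix(0, nrow(r), ncol(r))
  out[r >= pi / 2] <- 1
  mid <- r > pi / 4 & r < pi / 2
  out[mid] <- sin(pi / 2 * log2(4 * r[mid] / pi))
  out
}

# angular lobes: beta * cos(theta - theta_o)^(O-1) on a half-plane, with
# beta chosen so that the two-sided average of summed squared lobes is 1
.angular_masks <- function(theta, n_orientations) {
  O <- n_orientations
  cO <- O * choose(2 * (O - 1), O - 1) / 4^(O - 1)
  beta <- sqrt(2 / cO)
  lapply(seq_len(O), function(o) {
    d <- ((theta - (o - 1) * pi / O + pi) %% (2 * pi)) - pi
    a <- matrix(0, nrow(theta), ncol(theta))
    keep <- abs(d) < pi / 2
    a[keep] <- beta * cos(d[keep])^(O - 1)
    a
  })
}

# per-size mask set used at one pyramid level
.level_masks <- function(n, n_orientations) {
  key <- paste0(n, ".", n_orientations)
  hit <- .mask_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- .freq_axis(n)
  fx <- matrix(f, n, n, byrow = TRUE)
  fy <- matrix(f, n, n)
  r <- sqrt(fx^2 + fy^2)
  theta <- atan2(fy, fx)
  m <- list(
    lo  = .radial_lo(r),
    hi  = .radial_hi(r),
    lo0 = .radial_lo(r / 2),
    hi0 = .radial_hi(r / 2),
    ang = .angular_masks(theta, n_orientations)
  )
  assign(key, m, envir = .mask_cache)
  m
}

.ifft2 <- function(X) stats::fft(X, inverse = TRUE) / length(X)

# central spectrum crop: n -> n/2 (downsample by 2; image-value convention)
.spec_crop <- function(M) {
  n <- nrow(M)
  idx <- c(1:(n / 4), (n - n / 4 + 1):n)
  M[idx, idx] / 4
}

# zero-pad spectrum: n -> 2n (upsample by 2; image-value convention)
.spec_pad <- function(M) {
  n <- nrow(M)
  out <- matrix(0 + 0i, 2 * n, 2 * n)
  idx <- c(1:(n / 2), (2 * n - n / 2 + 1):(2 * n))
  out[idx, idx] <- M * 4
  out
}

# T(-omega) for an FFT-layout matrix
.flip_freq <- function(M) {
  n <- nrow(M)
  M[c(1, n:2), c(1, n:2)]
}

#' Build a complex steerable pyramid
#'
#' Decomposes a square grayscale image into `n_scales` x `n_orientations`
#' complex oriented bandpass coefficient grids plus real highpass and
#' lowpass residuals.  The real part of each complex band is the response
#' of an even-symmetric oriented filter and the imaginary part the response
#' of its Hilbert pair, so the modulus is a phase-invariant local energy
#' measure (a model complex cell).  The filters tile the Fourier domain and
#' the transform is a tight frame: [reconstruct()] inverts it to numerical
#' precision.
#'
#' Bands at scale k are stored spatially downsampled by `2^(k-1)` in image
#' units (a constant image yields a lowpass residual with the same mean).
#' The intermediate lowpass image entering each level (frequencies below the
#' level's bandpass) is retained in `$plow`; these "partial lowpass
#' reconstructions" carry the linear (simple-cell-like) signal on which
#' spatial covariance statistics are measured.
#'
#' @param image numeric square matrix, side divisible by `2^n_scales`.
#' @param n_scales number of scales K (>= 1).
#' @param n_orientations number of orientations O (>= 2).
#' @return An object of class `texpyr`: list with `bands` (list of K lists
#'   of O complex matrices), `highpass`, `lowpass`, `plow`, `n_scales`,
#'   `n_orientations`, `source_shape`.
#' @seealso [reconstruct()], [magnitude_responses()],
#'   [phase_doubled_responses()], [pyr_energy()]
#' @export
build_pyramid <- function(image, n_scales = 4L, n_orientations = 4L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix")
  n <- nrow(image)
  if (ncol(image) != n)
    stop("`image` must be square")
  if (n_scales < 1L) stop("`n_scales` must be >= 1")
  if (n_orientations < 2L) stop("`n_orientations` must be >= 2")
  if (n %% (2^n_scales) != 0L || n < 2^(n_scales + 1))
    stop("image side must be divisible by 2^n_scales (and large enough)")
  K <- as.integer(n_scales); O <- as.integer(n_orientations)

  X <- stats::fft(image)
  m0 <- .level_masks(n, O)
  highpass <- Re(.ifft2(m0$hi0 * X))
  S <- m0$lo0 * X

  bands <- vector("list", K)
  plow <- vector("list", K)
  for (k in seq_len(K)) {
    nk <- n / 2^(k - 1)
    mk <- .level_masks(nk, O)
    plow[[k]] <- Re(.ifft2(S))
    bk <- vector("list", O)
    HS <- mk$hi * S
    for (o in seq_len(O)) bk[[o]] <- .ifft2(mk$ang[[o]] * HS)
    bands[[k]] <- bk
    S <- .spec_crop(mk$lo * S)
  }
  lowpass <- Re(.ifft2(S))

  structure(
    list(bands = bands, highpass = highpass, lowpass = lowpass, plow = plow,
         n_scales = K, n_orientations = O, source_shape = c(n, n)),
    class = "texpyr")
}

print.texpyr <- function(x, ...) {
  cat(sprintf("complex steerable pyramid: %d x %d image, %d scales x %d orientations\n",
              x$source_shape[1], x$source_shape[2], x$n_scales, x$n_orientations))
  invisible(x)
}

.check_pyr <- function(coeffs) {
  if (!inherits(coeffs, "texpyr")) stop("expected a `texpyr` object")
  n <- coeffs$source_shape[1]
  for (k in seq_len(coeffs$n_scales)) {
    nk <- n / 2^(k - 1)
    for (o in seq_len(coeffs$n_orientations))
      if (nrow(coeffs$bands[[k]][[o]]) != nk)
        stop("band shapes inconsistent with source shape")
  }
  invisible(TRUE)
}

#' Invert a steerable pyramid
#'
#' Reconstructs the image from pyramid coefficients.  For coefficients
#' produced by [build_pyramid()] the round trip is exact to numerical
#' precision (tight frame); arbitrary (e.g. modified) coefficients are
#' mapped through the synthesis filters, which is also the adjoint of the
#' analysis operator up to the decimation weights.
#'
#' @param coeffs a `texpyr` object.
#' @return numeric matrix with the source dimensions.
#' @export
reconstruct <- function(coeffs) {
  .check_pyr(coeffs)
  K <- coeffs$n_scales; O <- coeffs$n_orientations
  n <- coeffs$source_shape[1]
  S <- stats::fft(coeffs$lowpass)
  for (k in K:1) {
    nk <- n / 2^(k - 1)
    mk <- .level_masks(nk, O)
    S <- mk$lo * .spec_pad(S)
    T <- matrix(0 + 0i, nk, nk)
    for (o in seq_len(O))
      T <- T + mk$ang[[o]] * stats::fft(coeffs$bands[[k]][[o]])
    T <- mk$hi * T
    S <- S + (T + Conj(.flip_freq(T))) / 2
  }
  m0 <- .level_masks(n, O)
  Re(.ifft2(m0$lo0 * S + m0$hi0 * stats::fft(coeffs$highpass)))
}

#' Coefficient energy of a decimated tight frame
#'
#' Computes the Parseval sum of squared pyramid coefficients in the
#' unit-norm-atom convention: bands stored at scale k are decimated
#' `(k-1)` times, so their squared values are weighted by `4^(k-1)` (and
#' the lowpass residual by `4^K`).  For any real input image,
#' `pyr_energy(build_pyramid(x)) == sum(x^2)` up to numerical precision.
#'
#' @param coeffs a `texpyr` object.
#' @return scalar total coefficient energy.
#' @export
pyr_energy <- function(coeffs) {
  .check_pyr(coeffs)
  e <- sum(coeffs$highpass^2) + 4^coeffs$n_scales * sum(coeffs$lowpass^2)
  for (k in seq_len(coeffs$n_scales)) {
    w <- 4^(k - 1)
    for (o in seq_len(coeffs$n_orientations))
      e <- e + w * sum(Mod(coeffs$bands[[k]][[o]])^2)
  }
  e
}

#' Magnitude (complex-cell) responses
#'
#' Modulus of each complex oriented band: the square root of the summed
#' squared responses of the even-symmetric filter and its Hilbert pair.
#' Invariant to the sign (and more generally the local phase) of the
#' bandpass content.
#'
#' @param coeffs a `texpyr` object.
#' @return list of K lists of O nonnegative real matrices.
#' @export
magnitude_responses <- function(coeffs) {
  .check_pyr(coeffs)
  lapply(coeffs$bands, function(bk) lapply(bk, Mod))
}

#' Phase-doubled coarse-scale responses
#'
#' Doubles the phase angle of each complex band at scales 2..K (magnitude
#' preserved) and upsamples the result by 2 with frequency-domain
#' interpolation so that the coarser scale aligns with the next finer
#' scale.  These maps enter the cross-scale phase statistics: because local
#' phase advances at half the rate at the coarser scale, doubling it makes
#' fine and coarse phases directly comparable (sensitive to edge polarity
#' and phase alignment across scale).
#'
#' @param coeffs a `texpyr` object with at least 2 scales.
#' @return list indexed by fine scale `k = 1..K-1`, each a list of O
#'   complex matrices at the fine scale's resolution (phase-doubled,
#'   upsampled scale `k+1` bands).
#' @export
phase_doubled_responses <- function(coeffs) {
  .check_pyr(coeffs)
  if (coeffs$n_scales < 2L)
    stop("phase-doubled cross-scale responses require at least 2 scales")
  K <- coeffs$n_scales
  out <- vector("list", K - 1L)
  for (k in seq_len(K - 1L)) {
    out[[k]] <- lapply(coeffs$bands[[k + 1L]], function(b) {
      m <- Mod(b)
      pd <- b
      nz <- m > 0
      pd[nz] <- b[nz]^2 / m[nz]
      pd[!nz] <- 0
      .upsample2_complex(pd)
    })
  }
  out
}

# frequency-domain 2x upsampling of a complex map (value convention)
.upsample2_complex <- function(z) {
  .ifft2(.spec_pad(stats::fft(z)))
}

.upsample2_real <- function(z) {
  Re(.ifft2(.spec_pad(stats::fft(z))))
}
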