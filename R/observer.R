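## The pooling observer: local statistic responses pooled under the window
## geometry, per-statistic rescaling calibrated on a broadband image
## ensemble, global Euclidean-norm normalization (divisive gain control),
## additive Gaussian response noise, the AXB distance decision, and SNR
## calibration of the noise level.

# precomputed per-geometry machinery: full-resolution window matrix plus
# block-averaged copies at each band resolution
.geom_context <- function(geom, n_scales) {
  W <- window_weights(geom)
  n <- geom$field_px
  P <- geom$n_windows
  Wk <- vector("list", n_scales)
  # windows have compact support: sparse storage makes the pooled
  # weighted averages cheap even for many small windows (small s)
  Wk[[1]] <- methods::as(W, "CsparseMatrix")
  row_i <- rep(seq_len(n), n)
  col_i <- rep(seq_len(n), each = n)
  for (k in 2:n_scales) {
    f <- 2L^(k - 1L)
    m <- n %/% f
    cell <- ((col_i - 1L) %/% f) * m + ((row_i - 1L) %/% f) + 1L
    Wc <- t(rowsum(t(W), cell, reorder = TRUE)) / f^2
    Wk[[k]] <- methods::as(Wc, "CsparseMatrix")
  }
  mass <- lapply(Wk, Matrix::rowSums)
  list(W = Wk[[1]], Wk = Wk, mass = mass, in_field_mass = Matrix::rowSums(W),
       P = P, n = n)
}

# P x 668 pooled statistics for one field image (catalog order)
.pooled_stats <- function(pyr, ctx, neighborhood = 7L) {
  K <- pyr$n_scales; O <- pyr$n_orientations
  off <- .offsets(neighborhood)
  no <- nrow(off)
  P <- ctx$P
  maps <- .stat_maps(pyr)

  wm <- function(k, cols) {  # weighted means: P x ncol
    as.matrix(ctx$Wk[[k]] %*% cols) / ctx$mass[[k]]
  }
  cov_block <- function(k, q) {  # P x no covariances of one map
    npix <- length(q)
    Pr <- matrix(0, npix, no); Sh <- matrix(0, npix, no)
    qv <- as.vector(q)
    for (i in seq_len(no)) {
      s <- as.vector(.cshift(q, off[i, 1], off[i, 2]))
      Pr[, i] <- qv * s
      Sh[, i] <- s
    }
    Ep <- wm(k, Pr); Es <- wm(k, Sh)
    Ep - Es * Es[, 1]   # column 1 is the zero offset: Es[,1] = E[q]
  }

  nlin <- K * no
  nmag <- K * O * no
  nmcs <- (K - 1) * O * O
  nmco <- K * choose(O, 2)
  nphs <- (K - 1) * O * O * 2
  out <- matrix(0, P, nlin + nmag + nmcs + nmco + nphs)

  # linear cross-position
  for (k in 1:K)
    out[, (k - 1) * no + seq_len(no)] <- cov_block(k, maps$p[[k]])
  base <- nlin
  # magnitude cross-position
  for (k in 1:K) for (o in 1:O)
    out[, base + ((k - 1) * O + o - 1) * no + seq_len(no)] <-
      cov_block(k, maps$mags[[k]][[o]])
  base <- nlin + nmag
  # magnitude cross-scale (fine k vs upsampled coarse k+1)
  for (k in 1:(K - 1)) {
    Em <- wm(k, vapply(1:O, function(o) as.vector(maps$mags[[k]][[o]]),
                       numeric(length(maps$mags[[k]][[1]]))))
    Emu <- wm(k, vapply(1:O, function(o) as.vector(maps$mu[[k]][[o]]),
                        numeric(length(maps$mu[[k]][[1]]))))
    for (of in 1:O) for (oc in 1:O) {
      col <- base + ((k - 1) * O + of - 1) * O + oc
      pr <- wm(k, as.vector(maps$mags[[k]][[of]] * maps$mu[[k]][[oc]]))
      out[, col] <- pr - Em[, of] * Emu[, oc]
    }
  }
  base <- nlin + nmag + nmcs
  # magnitude cross-orientation
  col <- base
  for (k in 1:K) {
    Em <- wm(k, vapply(1:O, function(o) as.vector(maps$mags[[k]][[o]]),
                       numeric(length(maps$mags[[k]][[1]]))))
    for (o1 in 1:(O - 1)) for (o2 in (o1 + 1):O) {
      col <- col + 1L
      pr <- wm(k, as.vector(maps$mags[[k]][[o1]] * maps$mags[[k]][[o2]]))
      out[, col] <- pr - Em[, o1] * Em[, o2]
    }
  }
  base <- nlin + nmag + nmcs + nmco
  # linear-phase cross-scale
  for (k in 1:(K - 1)) for (of in 1:O) {
    b <- maps$bands[[k]][[of]]
    for (oc in 1:O) {
      pr <- b * Conj(maps$pu[[k]][[oc]])
      col <- base + (((k - 1) * O + of - 1) * O + oc - 1) * 2
      out[, col + 1L] <- wm(k, as.vector(Re(pr)))
      out[, col + 2L] <- wm(k, as.vector(Im(pr)))
    }
  }
  out
}

#' Pooled observer responses to a field image
#'
#' Builds the steerable pyramid of the full model field and computes the
#' 668 observer statistics of every pooling window as spatially weighted
#' averages (window weight maps block-averaged to each band's resolution).
#'
#' @param field_image square image matrix covering the model field.
#' @param geom a `poolgeom` from [build_windows()] for the same field
#'   size.
#' @param neighborhood odd spatial neighborhood width (default 7).
#' @param n_scales,n_orientations pyramid configuration (default 4 x 4).
#' @param ctx optional precomputed geometry context (internal; lets
#'   callers reuse the window matrices across stimuli).
#' @return `P x 668` matrix of raw pooled statistics (rows = windows,
#'   columns in [statistic_catalog()] order).
#' @export
pooled_responses <- function(field_image, geom, neighborhood = 7L,
                             n_scales = 4L, n_orientations = 4L, ctx = NULL) {
  if (nrow(field_image) != geom$field_px || ncol(field_image) != geom$field_px)
    stop("field image does not match the geometry's field size")
  if (is.null(ctx)) ctx <- .geom_context(geom, n_scales)
  pyr <- build_pyramid(field_image, n_scales, n_orientations)
  .pooled_stats(pyr, ctx, neighborhood)
}

#' Embed a vignetted stimulus patch in the model field
#'
#' Places the patch so that its inner (top) edge lies at `ecc_deg` degrees
#' from fixation along the meridian through the field center, horizontally
#' centered; the rest of the field is background gray.
#'
#' @param patch vignetted square stimulus (from [crop_and_vignette()]).
#' @param field_px field side in pixels.
#' @param px_per_deg pixels per degree.
#' @param fixation fixation pixel coordinates (x, y).
#' @param ecc_deg inner-edge eccentricity in degrees.
#' @param background background gray level.
#' @return `field_px` x `field_px` matrix.
#' @export
embed_stimulus <- function(patch, field_px, px_per_deg, fixation,
                           ecc_deg = 4, background = 0.5) {
  n <- as.integer(field_px)
  w <- nrow(patch)
  top_edge <- ecc_deg * px_per_deg + fixation[2]
  r0 <- as.integer(round(top_edge))
  c0 <- (n - w) %/% 2L
  if (r0 < 0L || r0 + w > n || c0 < 0L)
    stop("stimulus does not fit inside the field at this eccentricity")
  field <- matrix(background, n, n)
  field[r0 + seq_len(w), c0 + seq_len(w)] <- patch
  field
}

# aperture support of an embedded stimulus, as a field map
.aperture_field <- function(width, field_px, px_per_deg, fixation, ecc_deg,
                            flat_frac = 7 / 8) {
  embed_stimulus(aperture_mask(width, flat_frac), field_px, px_per_deg,
                 fixation, ecc_deg, background = 0)
}

#' Window coverage / overlap with a stimulus aperture
#'
#' Inner product of each window's weight map with the stimulus aperture
#' transmission map, divided either by the window's in-field mass
#' (`"in_field"`: the fraction of usable window mass on the stimulus,
#' used to select windows for SNR calibration) or by the full continuous
#' window integral (`"total"`: the overlap proportion of the
#' single-region analysis).
#'
#' @param geom a `poolgeom`.
#' @param aperture_field field-sized aperture transmission map.
#' @param denominator `"in_field"` or `"total"`.
#' @param ctx optional geometry context.
#' @return numeric vector, one value per window.
#' @export
window_coverage <- function(geom, aperture_field,
                            denominator = c("in_field", "total"), ctx = NULL) {
  denominator <- match.arg(denominator)
  W <- if (!is.null(ctx)) ctx$W else window_weights(geom)
  num <- as.numeric(W %*% as.vector(aperture_field))
  den <- if (denominator == "in_field") as.numeric(Matrix::rowSums(W))
         else geom$centers$mass_total
  num / den
}

#' Calibrate per-statistic rescaling factors
#'
#' Measures pooled observer responses to an ensemble of broadband images
#' and returns the standard deviation of each statistic across all
#' (image, window) pairs.  Dividing responses by these factors equalizes
#' the very different numeric ranges of the statistic groups.  By default
#' the ensemble images (zero mean, unit variance) are first mapped into
#' the package gray-level convention (mean 0.5, sd 0.15) so the factors
#' are on the same response scale as the experimental stimuli.
#'
#' @param ensemble list of image matrices (e.g. from
#'   [make_calibration_ensemble()]); images are resized by centered
#'   cropping/tiling if they do not match the field.
#' @param geom a `poolgeom` (conventionally built with s = 0.5).
#' @param neighborhood statistic neighborhood width.
#' @param min_images minimum ensemble size (default 50; configurable).
#' @param standardize map images to gray-level convention first.
#' @param ctx optional geometry context.
#' @return positive numeric vector of length 668 (catalog order).
#' @export
calibrate_rescaling <- function(ensemble, geom, neighborhood = 7L,
                                min_images = 50L, standardize = TRUE,
                                ctx = NULL) {
  if (length(ensemble) < min_images)
    stop(sprintf("calibration ensemble has %d images; need at least %d",
                 length(ensemble), min_images))
  if (is.null(ctx)) ctx <- .geom_context(geom, 4L)
  n <- geom$field_px
  resp <- lapply(ensemble, function(img) {
    if (nrow(img) != n) img <- .fit_to_field(img, n)
    if (standardize) img <- 0.5 + 0.15 * (img - mean(img)) / stats::sd(img)
    pooled_responses(img, geom, neighborhood, ctx = ctx)
  })
  R <- do.call(rbind, resp)
  sds <- apply(R, 2, stats::sd)
  if (any(sds <= 0))
    stop("degenerate calibration ensemble: some statistics have zero variance")
  sds
}

# centered crop or toroidal tiling to fit an image to the field size
.fit_to_field <- function(img, n) {
  m <- nrow(img)
  if (m >= n) {
    i0 <- (m - n) %/% 2L
    img[i0 + seq_len(n), i0 + seq_len(n)]
  } else {
    reps <- ceiling(n / m)
    big <- do.call(rbind, rep(list(do.call(cbind, rep(list(img), reps))), reps))
    big[seq_len(n), seq_len(n)]
  }
}

#' Rescale, normalize and corrupt a response matrix
#'
#' Divides raw pooled statistics elementwise by the per-statistic rescale
#' vector, optionally divides the whole matrix by its global Euclidean
#' norm over all windows and statistics (divisive normalization; the
#' normalized matrix has unit Frobenius norm), and adds i.i.d. Gaussian
#' noise of standard deviation `sigma`.  Deterministic given the R random
#' seed.
#'
#' @param raw `P x N` raw response matrix.
#' @param rescale length-N positive vector (or NULL to skip).
#' @param sigma noise standard deviation (>= 0).
#' @param normalization_on apply the global Euclidean-norm division.
#' @return response matrix with attributes `sigma`, `normalized`.
#' @export
normalize_and_noise <- function(raw, rescale = NULL, sigma = 0,
                                normalization_on = TRUE) {
  stopifnot(sigma >= 0)
  R <- raw
  if (!is.null(rescale)) R <- sweep(R, 2, rescale, "/")
  if (normalization_on) {
    nrm <- sqrt(sum(R^2))
    if (nrm == 0)
      stop("zero-norm response cannot be normalized (blank stimulus?)")
    R <- R / nrm
  }
  if (sigma > 0)
    R <- R + matrix(stats::rnorm(length(R), 0, sigma), nrow(R))
  attr(R, "sigma") <- sigma
  attr(R, "normalized") <- normalization_on
  R
}

#' AXB distance decision
#'
#' Computes the Euclidean distances `D_A = ||R_A - R_X||` and
#' `D_B = ||R_B - R_X||` over all windows and statistics, and reports
#' which stimulus is judged the odd one: the one farther from X (X
#' matches the nearer stimulus).  Exact ties are broken by a fair coin
#' using the current random stream.
#'
#' @param R_A,R_X,R_B response matrices of matched dimensions.
#' @return `"A"` or `"B"`.
#' @export
decide_axb <- function(R_A, R_X, R_B) {
  dA <- sqrt(sum((R_A - R_X)^2))
  dB <- sqrt(sum((R_B - R_X)^2))
  if (dA > dB) "A" else if (dB > dA) "B"
  else if (stats::runif(1) < 0.5) "A" else "B"
}

#' Observer signal-to-noise ratio, and noise calibration
#'
#' `compute_snr` takes the responses of all experimental stimuli
#' restricted to pooling regions that cover the stimulus (rows of
#' `responses`), computes the variance of each statistic across those
#' rows, divides by `sigma^2`, and averages over statistics.
#' `calibrate_sigma` inverts this: it returns the `sigma` for which the
#' mean SNR equals `target_snr`.
#'
#' @param responses matrix of responses; rows are (stimulus, covered
#'   window) pairs, columns statistics.
#' @param sigma noise standard deviation.
#' @return mean SNR (scalar).
#' @export
compute_snr <- function(responses, sigma) {
  stopifnot(nrow(responses) >= 2, sigma > 0)
  mean(apply(responses, 2, stats::var)) / sigma^2
}

#' @rdname compute_snr
#' @param target_snr desired mean SNR.
#' @export
calibrate_sigma <- function(responses, target_snr) {
  stopifnot(nrow(responses) >= 2, target_snr > 0)
  sqrt(mean(apply(responses, 2, stats::var)) / target_snr)
}
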