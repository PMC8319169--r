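## Texture synthesis: generate images matching a target statistic vector by
## iterative adjustment of an initially white-noise image, plus stimulus
## preparation (cropping and raised-cosine vignetting).

#' Synthesize a texture image matching target statistics
#'
#' Starting from seeded Gaussian white noise, iteratively adjusts the image
#' until its full statistic vector (see [full_statistics()]) matches the
#' target.  Each iteration runs a bounded quasi-Newton (L-BFGS) cycle on a
#' least-squares objective over the statistic groups, with analytic
#' gradients propagated through the pyramid; before the first iteration the
#' noise is pre-conditioned by rescaling each oriented band to the target
#' band energy.  Convergence is declared when every statistic group matches
#' with relative error (L2, per group) at most `tol`.
#'
#' The result is deterministic given `seed`; different seeds yield
#' different samples with the same statistics (a texture family).
#'
#' @param target a `texstats` object from [full_statistics()].
#' @param size_px side of the synthesized square image; divisible by
#'   `2^n_scales`.
#' @param seed integer noise seed.
#' @param max_iters maximum number of optimizer cycles (default 50).
#' @param tol per-group relative error tolerance (default 1e-2).
#' @param inner_maxit L-BFGS updates per cycle.
#' @param verbose print per-cycle diagnostics.
#' @return the synthesized image matrix, with attributes `group_err`
#'   (named per-group relative errors), `iterations`, and `converged`.
#'   Non-convergence raises a warning with the achieved errors, never
#'   fails silently.
#' @export
synthesize <- function(target, size_px, seed, max_iters = 50L, tol = 1e-2,
                       inner_maxit = 30L, verbose = FALSE) {
  tv <- target$values
  t_mean <- unname(tv["mar_mean"])
  t_var <- unname(tv["mar_var"])

  set.seed(as.integer(seed))
  # coarse-to-fine: solve first at reduced resolution against the
  # scale-shifted target (content at stage scale k corresponds to final
  # scale k + j), then upsample and refine.  If the seeded noise already
  # sits near the target (e.g. a noise-like target), skip the coarse
  # stages: the full-resolution problem is then a short refinement.
  jmax <- 0L
  while (size_px / 2^(jmax + 1) >= 64 && target$n_scales - (jmax + 1) >= 2L)
    jmax <- jmax + 1L
  if (jmax > 0L) {
    plan0 <- .synth_plan(target, size_px)
    x0 <- matrix(stats::rnorm(size_px^2, t_mean, sqrt(t_var)), size_px)
    x0 <- .prematch_bands(x0, target)
    if (all(.synth_eval_fast(x0, plan0)$group_err <= 10 * tol)) jmax <- 0L
    set.seed(as.integer(seed))   # identical stream for the chosen path
  }
  x <- NULL
  iters_final <- 0L
  for (j in jmax:0) {
    n_s <- size_px / 2^j
    tgt_s <- if (j == 0L) target else .stage_target(target, j)
    plan <- .synth_plan(tgt_s, n_s)
    if (is.null(x)) {
      x <- matrix(stats::rnorm(n_s^2, t_mean, sqrt(t_var)), n_s)
      x <- .prematch_bands(x, tgt_s)
    } else {
      x <- .upsample2_real(x)
      x <- .prematch_bands(x, tgt_s)
    }
    cache <- new.env(parent = emptyenv())
    cache$par <- NULL
    evalx <- function(par) {
      if (is.null(cache$par) || !identical(par, cache$par)) {
        cache$res <- .synth_eval_fast(matrix(par, n_s), plan)
        cache$par <- par
      }
      cache$res
    }
    fn <- function(par) evalx(par)$loss
    gr <- function(par) as.vector(evalx(par)$grad)

    par <- as.vector(x)
    # coarse stages only initialize the next one: looser gate, small budget
    budget <- if (j == 0L) max_iters else min(max_iters, 8L)
    stage_tol <- if (j == 0L) tol else 1.5 * tol
    it <- 0L
    gden0 <- plan$gden
    gerr <- evalx(par)$group_err
    while (it < budget && any(gerr > stage_tol)) {
      # re-weight lagging statistic groups between cycles
      mult <- pmin(25, pmax(1, (gerr / stage_tol)^2))
      plan$gden <- gden0 / mult
      cache$par <- NULL
      opt <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                          control = list(maxit = inner_maxit, factr = 1e4))
      par <- opt$par
      it <- it + 1L
      gerr <- evalx(par)$group_err
      if (verbose)
        message(sprintf("stage %d iter %2d  loss %.3e  max group err %.3e",
                        j, it, opt$value, max(gerr)))
    }
    plan$gden <- gden0
    if (j == 0L) iters_final <- it
    x <- matrix(par, n_s)
  }
  converged <- all(gerr <= tol)
  if (!converged)
    warning(sprintf(
      "synthesis did not reach tol %.1e in %d iterations (worst group %s: %.3e)",
      tol, iters_final, names(gerr)[which.max(gerr)], max(gerr)))
  attr(x, "group_err") <- gerr
  attr(x, "iterations") <- iters_final
  attr(x, "converged") <- converged
  x
}

# target statistics for a coarse synthesis stage: scales j+1..K of the
# final target re-indexed as 1..K-j, with the marginal variance replaced
# by the zero-lag linear covariance at scale j+1 (the variance of the
# bandlimited image the stage represents)
.stage_target <- function(target, j) {
  K <- target$n_scales; O <- target$n_orientations; nb <- target$neighborhood
  Ks <- K - j
  stopifnot(Ks >= 2L)
  lab <- .full_labels(Ks, O, nb)
  src <- lab
  src$scale <- src$scale + j
  src$scale2 <- src$scale2 + j
  ids <- .stat_ids(src)
  vals <- unname(target$values[ids])
  m <- lab$group == "marginal"
  vals[m][1] <- unname(target$values["mar_mean"])
  vals[m][2] <- unname(target$values[sprintf("lin_s%d_d0.0", j + 1)])
  vals[m][3] <- unname(target$values["mar_skew"])
  vals[m][4] <- unname(target$values["mar_kurtosis"])
  .new_texstats(vals, lab, Ks, O, nb)
}

# rescale oriented bands (and the lowpass residual) of a noise image so
# that band energies match the target's; a cheap spectral pre-conditioner
.prematch_bands <- function(x, target) {
  K <- target$n_scales; O <- target$n_orientations
  pyr <- build_pyramid(x, K, O)
  tv <- target$values
  for (k in 1:K) for (o in 1:O) {
    cov0 <- tv[sprintf("mag_s%d_o%d_d0.0", k, o)]
    bm <- tv[sprintf("bmm_s%d_o%d", k, o)]
    et <- max(cov0 + bm^2, 0)
    b <- pyr$bands[[k]][[o]]
    ec <- mean(Mod(b)^2)
    if (ec > 0) pyr$bands[[k]][[o]] <- b * sqrt(et / ec)
  }
  # lowpass: match the target variance of the coarsest partial lowpass
  lp <- pyr$lowpass
  tvar_K <- tv[sprintf("lin_s%d_d0.0", K)]
  cvar <- mean((lp - mean(lp))^2)
  if (cvar > 0 && is.finite(tvar_K) && tvar_K > 0) {
    lp <- (lp - mean(lp)) * sqrt(as.numeric(tvar_K) / cvar) + mean(lp)
    pyr$lowpass <- lp
  }
  y <- reconstruct(pyr)
  tm <- unname(tv["mar_mean"]); tsd <- sqrt(unname(tv["mar_var"]))
  (y - mean(y)) / stats::sd(y) * tsd + tm
}

#' Generate a texture family
#'
#' Measures the full statistic vector of a prototype image and synthesizes
#' `n_samples` images matching it, each initialized with a different noise
#' seed.  Statistics are matched globally over the full synthesized extent
#' (not within local windows), so samples share family statistics but
#' differ in detail.
#'
#' @param prototype square image matrix (the family's statistic source).
#' @param n_samples number of samples to synthesize.
#' @param base_seed seed of the first sample; sample i uses
#'   `base_seed + i - 1`.
#' @param size_px synthesized image side (default 512).
#' @param ... passed to [synthesize()] (`max_iters`, `tol`, ...).
#' @return list of image matrices (with per-sample synthesis attributes).
#' @export
make_family <- function(prototype, n_samples, base_seed, size_px = 512L, ...) {
  target <- full_statistics(prototype)
  lapply(seq_len(n_samples), function(i)
    synthesize(target, size_px, seed = base_seed + i - 1L, ...))
}

#' Raised-cosine circular aperture mask
#'
#' Transmission mask for a square patch of side `width`: 1 inside the flat
#' top (diameter `flat_frac * width`), a raised-cosine ramp out to radius
#' `width/2`, and 0 beyond.  Radially monotone nonincreasing; the mask is
#' 0.5 midway through the ramp.
#'
#' @param width patch side in pixels.
#' @param flat_frac fraction of the width covered by the flat top
#'   (default 7/8).
#' @return `width` x `width` matrix in `[0, 1]`.
#' @export
aperture_mask <- function(width, flat_frac = 7 / 8) {
  stopifnot(flat_frac > 0, flat_frac <= 1)
  ctr <- (width + 1) / 2
  d <- (seq_len(width) - ctr)
  rho <- sqrt(outer(d^2, d^2, "+"))
  r_flat <- flat_frac * width / 2
  r_edge <- width / 2
  m <- matrix(0, width, width)
  m[rho <= r_flat] <- 1
  ramp <- rho > r_flat & rho < r_edge
  m[ramp] <- 0.5 * (1 + cos(pi * (rho[ramp] - r_flat) / (r_edge - r_flat)))
  m
}

#' Crop a centered square patch and vignette it
#'
#' Extracts a centered `width x width` crop and blends it against the
#' background gray through a raised-cosine circular aperture
#' ([aperture_mask()]): values in the flat top pass unchanged, pixels at or
#' beyond radius `width/2` equal the background.
#'
#' @param image source image matrix.
#' @param width crop side in pixels (must fit inside the source).
#' @param flat_frac flat-top fraction of the aperture (default 7/8).
#' @param background gray level outside the aperture (default 0.5, the
#'   package's mid-gray convention; prototypes are normalized to this
#'   mean).
#' @return `width` x `width` vignetted image matrix.
#' @export
crop_and_vignette <- function(image, width, flat_frac = 7 / 8, background = 0.5) {
  n <- nrow(image)
  if (width > n || width > ncol(image))
    stop("crop width exceeds source image size")
  i0 <- (n - width) %/% 2L
  j0 <- (ncol(image) - width) %/% 2L
  patch <- image[i0 + seq_len(width), j0 + seq_len(width)]
  m <- aperture_mask(width, flat_frac)
  background + m * (patch - background)
}

#' Assemble a stimulus set manifest
#'
#' Indexes vignetted stimuli by family, sample, crop width and
#' eccentricity condition.  Following the standard configuration, stimuli
#' at greater eccentricities reuse the same pixel images with a
#' proportionally lower pixel density (dilation by the eccentricity
#' ratio), so angular diameter scales with eccentricity.
#'
#' @param families list of texture families (each a list of sample image
#'   matrices).
#' @param widths crop widths in pixels.
#' @param px_per_deg pixels per degree at the reference eccentricity.
#' @param eccentricities inner-edge eccentricities in degrees; the first is
#'   the reference.
#' @param flat_frac,background passed to [crop_and_vignette()].
#' @return list with `images` (nested list `[[family]][[sample]][[width]]`
#'   of vignetted patches) and `manifest` (data.frame with columns
#'   `family`, `sample`, `width_px`, `ecc_deg`, `px_per_deg`,
#'   `diameter_deg`).
#' @export
build_stimulus_set <- function(families, widths, px_per_deg = 80,
                               eccentricities = 4, flat_frac = 7 / 8,
                               background = 0.5) {
  images <- lapply(families, function(fam)
    lapply(fam, function(img) {
      out <- lapply(widths, function(w)
        crop_and_vignette(img, w, flat_frac, background))
      names(out) <- as.character(widths)
      out
    }))
  ecc0 <- eccentricities[1]
  manifest <- do.call(rbind, lapply(seq_along(eccentricities), function(ie) {
    ecc <- eccentricities[ie]
    ppd <- px_per_deg * ecc0 / ecc     # dilation: same pixels, lower density
    expand.grid(family = seq_along(families),
                sample = seq_along(families[[1]]),
                width_px = widths,
                ecc_deg = ecc, px_per_deg = ppd)
  }))
  manifest$diameter_deg <- manifest$width_px / manifest$px_per_deg
  list(images = images, manifest = manifest)
}
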