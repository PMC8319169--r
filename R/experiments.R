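## Simulation drivers: AXB discrimination of texture families and samples
## as a function of stimulus size, eccentricity sweeps, the normalization
## ablation, the single-pooling-region overlap analysis, and the
## statistic-convergence (coefficient of variation) analysis.

#' Observer responses to a stimulus set
#'
#' Embeds every vignetted stimulus of a set in the model field at the
#' given inner-edge eccentricity, computes pooled observer statistics for
#' every pooling window, rescales them, and returns both the normalized
#' (unit global norm) and unnormalized clean response vectors, together
#' with window coverage per stimulus width.
#'
#' @param stim_set output of [build_stimulus_set()].
#' @param geom a `poolgeom` for the model field.
#' @param rescale per-statistic rescale vector from
#'   [calibrate_rescaling()].
#' @param ecc_deg inner-edge eccentricity of the stimuli (degrees).
#' @param neighborhood statistic neighborhood width.
#' @param background field background gray.
#' @param ctx optional precomputed geometry context.
#' @return list with one element per width: `clean` (stimuli x (P*N)
#'   normalized response matrix, rows labelled by family/sample in
#'   `index`), `raw_rescaled` (same without normalization),
#'   `coverage_in_field` and `overlap_total` (per window), `P`, `N`,
#'   plus `index` (family/sample table) and `geom` metadata.
#' @export
observer_responses <- function(stim_set, geom, rescale, ecc_deg = 4,
                               neighborhood = 7L, background = 0.5,
                               ctx = NULL) {
  if (is.null(ctx)) ctx <- .geom_context(geom, 4L)
  widths <- names(stim_set$images[[1]][[1]])
  nf <- length(stim_set$images)
  ns <- length(stim_set$images[[1]])
  index <- expand.grid(sample = seq_len(ns), family = seq_len(nf))[, c("family", "sample")]
  out <- vector("list", length(widths))
  names(out) <- widths
  for (w in widths) {
    wpx <- as.integer(w)
    ap <- .aperture_field(wpx, geom$field_px, geom$px_per_deg, geom$fixation,
                          ecc_deg)
    cov_if <- window_coverage(geom, ap, "in_field", ctx = ctx)
    ov_tot <- window_coverage(geom, ap, "total", ctx = ctx)
    rows <- vector("list", nrow(index))
    raws <- vector("list", nrow(index))
    for (r in seq_len(nrow(index))) {
      patch <- stim_set$images[[index$family[r]]][[index$sample[r]]][[w]]
      field <- embed_stimulus(patch, geom$field_px, geom$px_per_deg,
                              geom$fixation, ecc_deg, background)
      raw <- pooled_responses(field, geom, neighborhood, ctx = ctx)
      rr <- sweep(raw, 2, rescale, "/")
      raws[[r]] <- as.vector(rr)
      rows[[r]] <- as.vector(rr / sqrt(sum(rr^2)))
    }
    out[[w]] <- list(clean = do.call(rbind, rows),
                     raw_rescaled = do.call(rbind, raws),
                     coverage_in_field = cov_if, overlap_total = ov_tot,
                     P = geom$n_windows, N = length(rescale))
  }
  list(per_width = out, index = index, ecc_deg = ecc_deg, s = geom$s,
       px_per_deg = geom$px_per_deg)
}

# rows of the (stimulus x window) response stack restricted to windows
# covering the stimulus; used for SNR calibration
.covered_rows <- function(resp, normalization_on = TRUE,
                          coverage_threshold = 0.01) {
  blocks <- lapply(resp$per_width, function(b) {
    keep <- which(b$coverage_in_field >= coverage_threshold)
    if (length(keep) == 0) return(NULL)
    M <- if (normalization_on) b$clean else b$raw_rescaled
    do.call(rbind, lapply(seq_len(nrow(M)), function(r) {
      matrix(M[r, ], b$P, b$N)[keep, , drop = FALSE]
    }))
  })
  do.call(rbind, blocks)
}

# exact reduced-dimension AXB trial sampler: conditions the noise on the
# 2-D span of the clean difference vectors; the squared distances in the
# orthogonal complement follow a 2x2 Wishart with M-2 degrees of freedom.
# Distributionally identical to drawing full M-dimensional noise.
.axb_trials_reduced <- function(G, a, b, x, correct_odd, sigma, M) {
  n <- length(a)
  uu <- G[cbind(a, a)] + G[cbind(x, x)] - 2 * G[cbind(a, x)]
  vv <- G[cbind(b, b)] + G[cbind(x, x)] - 2 * G[cbind(b, x)]
  uv <- G[cbind(a, b)] - G[cbind(a, x)] - G[cbind(x, b)] + G[cbind(x, x)]
  uu <- pmax(uu, 0); vv <- pmax(vv, 0)
  if (sigma == 0) {
    dA2 <- uu; dB2 <- vv
  } else {
    nu <- sqrt(uu)
    v1 <- ifelse(nu > 0, uv / nu, sqrt(vv))
    v2 <- sqrt(pmax(vv - v1^2, 0))
    z <- matrix(stats::rnorm(6 * n, 0, sigma), n)
    Wf <- stats::rWishart(n, M - 2, sigma^2 * matrix(c(2, 1, 1, 2), 2))
    dA2 <- (nu + z[, 1] - z[, 5])^2 + (z[, 2] - z[, 6])^2 + Wf[1, 1, ]
    dB2 <- (v1 + z[, 3] - z[, 5])^2 + (v2 + z[, 4] - z[, 6])^2 + Wf[2, 2, ]
  }
  choice <- ifelse(dA2 > dB2, "A", ifelse(dB2 > dA2, "B",
                                          ifelse(stats::runif(n) < 0.5, "A", "B")))
  choice == correct_odd
}

# direct sampler: full-dimensional noise and decide_axb(); used as a
# cross-check of the reduced sampler on small problems
.axb_trials_direct <- function(V, a, b, x, correct_odd, sigma) {
  n <- length(a)
  M <- ncol(V)
  vapply(seq_len(n), function(i) {
    RA <- V[a[i], ] + stats::rnorm(M, 0, sigma)
    RX <- V[x[i], ] + stats::rnorm(M, 0, sigma)
    RB <- V[b[i], ] + stats::rnorm(M, 0, sigma)
    decide_axb(RA, RX, RB) == correct_odd[i]
  }, logical(1))
}

# draw AXB trial compositions for one task
.draw_trials <- function(task, index, n_trials) {
  nf <- max(index$family); ns <- max(index$sample)
  row_of <- function(f, s) which(index$family == f & index$sample == s)
  rowmap <- matrix(0L, nf, ns)
  for (r in seq_len(nrow(index))) rowmap[index$family[r], index$sample[r]] <- r
  xside <- sample(rep(c(1L, 2L), length.out = n_trials))
  if (task == "sample") {
    if (ns < 2) stop("sample task needs >= 2 samples per family")
    f <- sample.int(nf, n_trials, replace = TRUE)
    s1 <- sample.int(ns, n_trials, replace = TRUE)
    s2 <- ((s1 - 1L + sample.int(ns - 1L, n_trials, replace = TRUE)) %% ns) + 1L
    a <- rowmap[cbind(f, s1)]
    b <- rowmap[cbind(f, s2)]
    x <- ifelse(xside == 1L, a, b)   # X is pixel-identical to one side
  } else if (task == "family") {
    if (nf < 2) stop("family task needs >= 2 families")
    if (ns < 2) stop("family task needs >= 2 samples per family")
    f1 <- sample.int(nf, n_trials, replace = TRUE)
    f2 <- ((f1 - 1L + sample.int(nf - 1L, n_trials, replace = TRUE)) %% nf) + 1L
    s1 <- sample.int(ns, n_trials, replace = TRUE)
    s2 <- sample.int(ns, n_trials, replace = TRUE)
    a <- rowmap[cbind(f1, s1)]
    b <- rowmap[cbind(f2, s2)]
    sx <- integer(n_trials)
    same <- xside == 1L
    # X: a different sample from the matching side's family
    sx[same] <- ((s1[same] - 1L + sample.int(ns - 1L, sum(same), replace = TRUE)) %% ns) + 1L
    sx[!same] <- ((s2[!same] - 1L + sample.int(ns - 1L, sum(!same), replace = TRUE)) %% ns) + 1L
    x <- ifelse(same, rowmap[cbind(f1, sx)], rowmap[cbind(f2, sx)])
  } else stop("unknown task")
  correct_odd <- ifelse(xside == 1L, "B", "A")
  list(a = a, b = b, x = x, correct_odd = correct_odd)
}

#' Simulate AXB discrimination for one condition
#'
#' Assembles `n_trials` AXB trials from the clean response vectors of a
#' stimulus set at one condition, corrupts them with Gaussian noise of
#' standard deviation `sigma`, applies the distance decision rule, and
#' returns the proportion correct.  In the family task A and B are
#' samples from different families and X another sample of one of them;
#' in the sample task A and B are different samples of one family and X a
#' pixel-identical copy of one of them.  The matching side is
#' counterbalanced.
#'
#' By default trials are simulated with an exact reduced-dimension
#' sampler (noise conditioned on the span of the clean differences, the
#' orthogonal remainder drawn from its Wishart law), which is
#' distributionally identical to drawing the full noise vectors;
#' `method = "direct"` does the latter via [decide_axb()].
#'
#' @param task `"family"` or `"sample"`.
#' @param V matrix of clean response vectors, one row per stimulus.
#' @param index data.frame with `family`, `sample` for the rows of `V`.
#' @param sigma noise standard deviation.
#' @param n_trials number of trials.
#' @param seed integer seed (trial draws and noise).
#' @param method `"reduced"` or `"direct"`.
#' @return one-row data.frame: `n_trials`, `n_correct`, `prop_correct`,
#'   `se` (binomial standard error).
#' @export
run_discrimination <- function(task, V, index, sigma, n_trials, seed,
                               method = c("reduced", "direct")) {
  method <- match.arg(method)
  set.seed(as.integer(seed))
  tr <- .draw_trials(task, index, n_trials)
  ok <- if (method == "reduced") {
    G <- tcrossprod(V)
    .axb_trials_reduced(G, tr$a, tr$b, tr$x, tr$correct_odd, sigma, ncol(V))
  } else {
    .axb_trials_direct(V, tr$a, tr$b, tr$x, tr$correct_odd, sigma)
  }
  nc <- sum(ok)
  p <- nc / n_trials
  data.frame(n_trials = n_trials, n_correct = nc, prop_correct = p,
             se = sqrt(p * (1 - p) / n_trials))
}

#' Size sweep: discrimination performance vs stimulus diameter
#'
#' For one pooling scaling (the geometry behind `resp`), calibrates the
#' noise level for each target SNR from the responses of all covered
#' windows across the stimulus set, then simulates family and sample
#' discrimination at every stimulus width.
#'
#' @param resp output of [observer_responses()].
#' @param snr_targets vector of mean-SNR targets (e.g. `c(0.125, 0.5, 2)`).
#' @param n_trials trials per condition.
#' @param seed integer seed.
#' @param normalization_on simulate with (TRUE) or without (FALSE) the
#'   global response normalization; sigma is recalibrated accordingly.
#' @param coverage_threshold minimum in-field window coverage for a
#'   window to count as "covering the stimulus" in the SNR computation.
#' @param method trial sampler, see [run_discrimination()].
#' @return PerformanceTable data.frame over task x width x SNR with the
#'   calibrated `sigma` per SNR.
#' @export
size_sweep <- function(resp, snr_targets = 0.5, n_trials = 2000L, seed = 1L,
                       normalization_on = TRUE, coverage_threshold = 0.01,
                       method = "reduced") {
  covered <- .covered_rows(resp, normalization_on, coverage_threshold)
  if (is.null(covered) || nrow(covered) < 2)
    stop("no pooling window covers any stimulus at the coverage threshold")
  rows <- list()
  for (si in seq_along(snr_targets)) {
    snr <- snr_targets[si]
    sigma <- calibrate_sigma(covered, snr)
    for (w in names(resp$per_width)) {
      b <- resp$per_width[[w]]
      V <- if (normalization_on) b$clean else b$raw_rescaled
      for (task in c("family", "sample")) {
        # common random numbers across stimulus sizes (paired design):
        # the same trial compositions and noise draws are reused for
        # every width within one task x SNR cell, so size effects are
        # not diluted by independent simulation noise
        pr <- run_discrimination(task, V, resp$index, sigma, n_trials,
                                 seed = seed + 1000L * si +
                                   (task == "sample"), method = method)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(task = task, width_px = as.integer(w),
                     diameter_deg = as.integer(w) / resp$px_per_deg,
                     ecc_deg = resp$ecc_deg, s = resp$s, snr = snr,
                     sigma = sigma, normalization = normalization_on), pr)
      }
    }
  }
  do.call(rbind, rows)
}

#' Crossover diameter of the family and sample performance curves
#'
#' Finds the stimulus diameter at which family and sample discrimination
#' accuracy are equal, by linear interpolation of their difference
#' against log diameter; `NA` if the curves do not cross.
#'
#' @param perf a PerformanceTable (one task pair, one condition set).
#' @return crossover diameter in degrees, or `NA`.
#' @export
crossover_diameter <- function(perf) {
  fam <- perf[perf$task == "family", ]
  smp <- perf[perf$task == "sample", ]
  fam <- fam[order(fam$diameter_deg), ]
  smp <- smp[order(smp$diameter_deg), ]
  stopifnot(all(fam$diameter_deg == smp$diameter_deg))
  d <- fam$prop_correct - smp$prop_correct
  ld <- log(fam$diameter_deg)
  # a crossover requires an actual flip: family strictly above sample
  # after having been at or below it (ties alone do not count)
  for (i in seq_len(length(d) - 1)) {
    if (d[i] <= 0 && d[i + 1] > 0) {
      t <- -d[i] / (d[i + 1] - d[i])
      return(exp(ld[i] + t * (ld[i + 1] - ld[i])))
    }
  }
  NA_real_
}

#' Eccentricity sweep
#'
#' Simulates the size sweep at several inner-edge eccentricities; for
#' eccentricities beyond the first, the same stimulus pixels are
#' presented dilated (pixel density divided by the eccentricity ratio),
#' so angular diameters scale proportionally.  The pooling geometry is
#' rebuilt for each condition's pixel density.
#'
#' @param stim_set output of [build_stimulus_set()].
#' @param field_px,px_per_deg,fixation field configuration at the
#'   reference eccentricity.
#' @param s pooling scaling factor.
#' @param rescale per-statistic rescale vector.
#' @param eccentricities inner-edge eccentricities (degrees); the first
#'   is the reference.
#' @param snr target mean SNR.
#' @param n_trials,seed simulation settings.
#' @return PerformanceTable over task x width x eccentricity, with a
#'   `crossover` attribute (named vector of crossover diameters).
#' @export
eccentricity_sweep <- function(stim_set, field_px, px_per_deg, fixation, s,
                               rescale, eccentricities = c(4, 8, 16),
                               snr = 0.5, n_trials = 2000L, seed = 1L) {
  ecc0 <- eccentricities[1]
  rows <- list()
  cross <- numeric(0)
  for (ecc in eccentricities) {
    ppd <- px_per_deg * ecc0 / ecc
    geom <- build_windows(field_px, ppd, fixation, s)
    ctx <- .geom_context(geom, 4L)
    resp <- observer_responses(stim_set, geom, rescale, ecc_deg = ecc,
                               ctx = ctx)
    perf <- size_sweep(resp, snr_targets = snr, n_trials = n_trials,
                       seed = seed + round(100 * ecc))
    rows[[length(rows) + 1L]] <- perf
    cross[as.character(ecc)] <- crossover_diameter(perf)
  }
  out <- do.call(rbind, rows)
  attr(out, "crossover") <- cross
  out
}

#' Single-pooling-region analysis
#'
#' Simulates discrimination based on the 668 statistics of one pooling
#' region at a time, as a function of the overlap between the region and
#' the stimulus aperture (inner product of window and aperture divided by
#' the window's full integral).  Stimuli are presented at several
#' inner-edge eccentricities at a fixed pixel density to vary the
#' relative size of windows and stimulus.  Accuracies are averaged over
#' windows, sizes and eccentricities within logarithmically spaced
#' overlap bins.
#'
#' Each window is treated as a complete (single-region) observer: its
#' rescaled 668-statistic response vector is normalized by its own
#' Euclidean norm before noise is added, mirroring the full model's
#' normalization with P = 1.
#'
#' @param stim_set output of [build_stimulus_set()].
#' @param geom pooling geometry (conventionally s = 0.6) whose field is
#'   large enough for the largest eccentricity.
#' @param rescale rescale vector.
#' @param eccentricities inner-edge eccentricities (degrees, fixed pixel
#'   density).
#' @param snr target mean SNR for the noise.
#' @param n_trials trials per (window, width, eccentricity, task) cell.
#' @param n_bins number of log-spaced overlap bins.
#' @param seed integer seed.
#' @param max_width_px optionally drop widths that do not fit at the
#'   larger eccentricities.
#' @return list: `by_bin` (data.frame bin, overlap range, task, mean
#'   accuracy, n cells), `cells` (per-cell table), `sigma`.
#' @export
single_region_analysis <- function(stim_set, geom, rescale,
                                   eccentricities = c(4, 8, 16), snr = 0.5,
                                   n_trials = 400L, n_bins = 10L, seed = 1L,
                                   max_width_px = Inf) {
  ctx <- .geom_context(geom, 4L)
  N <- length(rescale)
  P <- geom$n_windows
  resp_all <- list()
  for (ecc in eccentricities) {
    widths <- as.integer(names(stim_set$images[[1]][[1]]))
    widths <- widths[widths <= max_width_px |
                       ecc == eccentricities[1]]
    fit <- vapply(widths, function(w) {
      r0 <- round(ecc * geom$px_per_deg + geom$fixation[2])
      r0 >= 0 && r0 + w <= geom$field_px
    }, logical(1))
    widths <- widths[fit]
    if (length(widths) == 0) next
    sub <- stim_set
    sub$images <- lapply(sub$images, function(fam)
      lapply(fam, function(s) s[as.character(widths)]))
    resp_all[[as.character(ecc)]] <-
      observer_responses(sub, geom, rescale, ecc_deg = ecc, ctx = ctx)
  }
  # per-window unit-norm responses of every covered (window, stimulus)
  window_vectors <- function(b, i) {
    Vi <- b$raw_rescaled[, seq(i, by = b$P, length.out = N), drop = FALSE]
    nrm <- sqrt(rowSums(Vi^2))
    ok <- nrm > 0
    Vi[ok, ] <- Vi[ok, , drop = FALSE] / nrm[ok]
    Vi
  }
  covered <- do.call(rbind, lapply(resp_all, function(resp)
    do.call(rbind, lapply(resp$per_width, function(b) {
      keep <- which(b$coverage_in_field >= 0.01)
      do.call(rbind, lapply(keep, function(i) window_vectors(b, i)))
    }))))
  sigma <- calibrate_sigma(covered, snr)

  cells <- list()
  seed_i <- 0L
  for (ecc_name in names(resp_all)) {
    resp <- resp_all[[ecc_name]]
    for (w in names(resp$per_width)) {
      b <- resp$per_width[[w]]
      for (i in seq_len(b$P)) {
        ov <- b$overlap_total[i]
        if (ov <= 0) next
        Vi <- window_vectors(b, i)
        for (task in c("family", "sample")) {
          seed_i <- seed_i + 1L
          pr <- run_discrimination(task, Vi, resp$index, sigma,
                                   n_trials, seed = seed + seed_i)
          cells[[length(cells) + 1L]] <- data.frame(
            ecc_deg = as.numeric(ecc_name), width_px = as.integer(w),
            window = i, overlap = ov, task = task,
            prop_correct = pr$prop_correct, n_trials = n_trials)
        }
      }
    }
  }
  cells <- do.call(rbind, cells)
  lo <- max(min(cells$overlap), 1e-4)
  brk <- exp(seq(log(lo * 0.999), log(max(cells$overlap) * 1.001),
                 length.out = n_bins + 1L))
  cells$bin <- cut(cells$overlap, brk, labels = FALSE)
  by_bin <- do.call(rbind, lapply(split(cells, list(cells$bin, cells$task),
                                        drop = TRUE), function(d)
    data.frame(bin = d$bin[1], task = d$task[1],
               overlap_mid = exp(mean(log(range(d$overlap)))),
               prop_correct = mean(d$prop_correct), n_cells = nrow(d))))
  rownames(by_bin) <- NULL
  list(by_bin = by_bin[order(by_bin$task, by_bin$bin), ], cells = cells,
       sigma = sigma)
}

#' Statistic convergence with measurement region size
#'
#' For texture families whose samples share full-field statistics,
#' measures statistics from centered square crops of increasing width and
#' computes the coefficient of variation of each statistic across samples
#' (per family), summarizing the linear-product and magnitude-product
#' position-covariance classes by their median and interquartile range
#' across statistics and families.
#'
#' @param families list of families (each a list of sample images).
#' @param widths crop widths in pixels.
#' @param n_scales,n_orientations,neighborhood statistic configuration.
#' @return data.frame: `width_px`, `class`, `median_cv`, `q25`, `q75`.
#' @export
convergence_analysis <- function(families, widths, n_scales = 4L,
                                 n_orientations = 4L, neighborhood = 7L) {
  if (any(vapply(families, length, integer(1)) < 2))
    stop("each family needs at least 2 samples for a coefficient of variation")
  classes <- c(linear = "linear_cross_position",
               magnitude = "magnitude_cross_position")
  rows <- list()
  for (w in widths) {
    cvs <- list(linear = numeric(0), magnitude = numeric(0))
    for (fam in families) {
      stats_w <- lapply(fam, function(img) {
        n <- nrow(img)
        i0 <- (n - w) %/% 2L
        full_statistics(img[i0 + seq_len(w), i0 + seq_len(w)],
                        n_scales, n_orientations, neighborhood)
      })
      cv <- coefficient_of_variation(stats_w)
      for (cl in names(classes)) {
        v <- abs(cv$cv[cv$group == classes[[cl]]])
        cvs[[cl]] <- c(cvs[[cl]], v[is.finite(v)])
      }
    }
    for (cl in names(classes)) {
      q <- stats::quantile(cvs[[cl]], c(0.25, 0.5, 0.75), na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        width_px = w, class = cl, median_cv = q[2], q25 = q[1], q75 = q[3])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}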