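# Shared simulation fixtures, built lazily once per test session.
#
# The study profile used by the end-to-end tests: the standard
# configuration scaled down by 2 in pixels — 256^2 samples, a 320^2 field
# at 40 px/deg with fixation (160.5, -128), so the field still spans
# 8 x 8 degrees and the crop widths subtend the standard angular sizes —
# with 4 families x 5 samples at generator difficulty 0.5 and 2,000
# trials per condition.

.fx <- new.env(parent = emptyenv())

fx_field <- function() {
  list(field_px = 320L, px_per_deg = 40, fixation = c(160.5, -128),
       widths = c(32L, 64L, 96L, 160L, 256L))
}

fx_families <- function() {
  if (is.null(.fx$fams)) {
    protos <- make_prototypes(4, difficulty = 0.5, seed = 42, size_px = 256)
    .fx$fams <- lapply(seq_along(protos), function(i)
      suppressWarnings(make_family(protos[[i]], 5, base_seed = 100L * i,
                                   size_px = 256)))
  }
  .fx$fams
}

fx_stimuli <- function() {
  if (is.null(.fx$stim)) {
    fd <- fx_field()
    .fx$stim <- build_stimulus_set(fx_families(), widths = fd$widths,
                                   px_per_deg = fd$px_per_deg)
  }
  .fx$stim
}

fx_rescale <- function() {
  if (is.null(.fx$resc)) {
    fd <- fx_field()
    cal <- make_calibration_ensemble(50, fd$field_px, seed = 9)
    g05 <- build_windows(fd$field_px, fd$px_per_deg, fd$fixation, 0.5)
    .fx$resc <- calibrate_rescaling(cal, g05)
  }
  .fx$resc
}

fx_responses <- function(s) {
  key <- paste0("resp", s)
  if (is.null(.fx[[key]])) {
    fd <- fx_field()
    g <- build_windows(fd$field_px, fd$px_per_deg, fd$fixation, s)
    .fx[[key]] <- observer_responses(fx_stimuli(), g, fx_rescale(),
                                     ecc_deg = 4)
  }
  .fx[[key]]
}

fx_perf <- function(s, snr_targets = c(0.125, 0.5, 2), n_trials = 2000L) {
  key <- paste0("perf", s)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- size_sweep(fx_responses(s), snr_targets = snr_targets,
                             n_trials = n_trials, seed = 11)
  .fx[[key]]
}

# rescale vector for the single-region field (448 px at 40 px/deg)
fx_rescale_small <- function() {
  if (is.null(.fx$resc_small)) {
    cal <- make_calibration_ensemble(30, 448, seed = 9)
    g05 <- build_windows(448, 40, c(224.5, -128), 0.5)
    .fx$resc_small <- calibrate_rescaling(cal, g05, min_images = 30)
  }
  .fx$resc_small
}

# convergence-analysis families: 5 families x 15 samples at 128^2,
# matched to a 2% per-group tolerance
fx_cv_families <- function() {
  if (is.null(.fx$cvfams)) {
    protos <- make_prototypes(5, difficulty = 0.5, seed = 7, size_px = 128)
    .fx$cvfams <- lapply(seq_along(protos), function(i)
      suppressWarnings(make_family(protos[[i]], 15, base_seed = 1000L * i,
                                   size_px = 128, tol = 2e-2,
                                   max_iters = 10)))
  }
  .fx$cvfams
}

spearman <- function(x) suppressWarnings(stats::cor(x, seq_along(x),
                                                    method = "spearman"))
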