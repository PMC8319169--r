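## Eccentricity-scaled pooling windows.
##
## The model's visual field is tiled by smooth windows that are separable
## in log-eccentricity and polar angle about a fixation point outside the
## image.  Window profiles are squared-cosine bumps whose neighbors sum to
## one, so the full set forms an exact partition of unity; both the radial
## and angular full-widths grow in proportion to eccentricity, at a rate
## set by a single scaling factor s (full-width at half maximum divided by
## center eccentricity), with a radial:circumferential aspect ratio of
## about 2.

# squared-cosine bump with support |x| < delta; adjacent copies spaced by
# delta sum to 1, FWHM = delta
.bump <- function(x, delta) {
  out <- numeric(length(x))
  inside <- abs(x) < delta
  out[inside] <- cos(pi * x[inside] / (2 * delta))^2
  out
}

#' Construct eccentricity-scaled pooling windows
#'
#' Builds the pooling geometry for a square field of `field_px` pixels at
#' `px_per_deg`, with the fixation point at continuous pixel coordinates
#' `fixation` (x, y; pixel centers at integers 1..n) which must lie
#' outside the field.  Window centers sit on a log-eccentricity by
#' polar-angle grid with radial spacing `2*asinh(s/2)` (so the radial
#' FWHM at eccentricity e is `s * e`) and angular spacing half the radial
#' spacing (aspect ratio ~2).  The windows sum to exactly 1 at every field
#' pixel; windows with no pointwise support in the field (maximum weight
#' below `drop_threshold`) are omitted.
#'
#' @param field_px field side in pixels.
#' @param px_per_deg pixels per degree of visual angle.
#' @param fixation numeric length-2 (x, y) fixation pixel coordinates.
#' @param s scaling factor (window diameter / eccentricity), > 0.
#' @param drop_threshold windows whose maximum in-field weight is below
#'   this are dropped (default 1e-9, preserving the tiling identity).
#' @return object of class `poolgeom`: window center table (`centers`:
#'   `u` log-eccentricity, `ecc_deg`, `angle_rad`, `mass_total` full
#'   continuous integral in px^2), field maps (`u_map`, `angle_map`),
#'   spacing parameters, and field metadata.  Weight maps are evaluated
#'   lazily via [window_weights()].
#' @export
build_windows <- function(field_px, px_per_deg, fixation, s,
                          drop_threshold = 1e-9) {
  stopifnot(s > 0, length(fixation) == 2)
  n <- as.integer(field_px)
  fx <- fixation[1]; fy <- fixation[2]
  if (fx >= 0.5 && fx <= n + 0.5 && fy >= 0.5 && fy <= n + 0.5)
    stop("fixation point lies inside the field; eccentricity would vanish")
  xs <- seq_len(n)
  dx <- matrix(xs - fx, n, n, byrow = TRUE)
  dy <- matrix(xs - fy, n, n)
  ecc <- sqrt(dx^2 + dy^2) / px_per_deg
  u_map <- log(ecc)
  angle_map <- atan2(dx, dy)   # 0 points from fixation into the field

  de <- 2 * asinh(s / 2)
  ntheta <- max(4L, as.integer(round(2 * pi / (de / 2))))
  dth <- 2 * pi / ntheta

  u_min <- min(u_map); u_max <- max(u_map)
  mlo <- floor(-de / de)  # one ring below the nearest eccentricity
  M <- ceiling((u_max - u_min) / de)
  u_centers <- u_min + (-1:(M + 1)) * de
  th_centers <- -pi + (seq_len(ntheta) - 1L) * dth

  grid <- expand.grid(u = u_centers, angle = th_centers)
  # keep windows with pointwise support in the field
  keep <- logical(nrow(grid))
  maxw <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    wu <- .bump(u_map - grid$u[i], de)
    if (!any(wu > 0)) next
    dthw <- ((angle_map - grid$angle[i] + pi) %% (2 * pi)) - pi
    w <- wu * .bump(dthw, dth)
    maxw[i] <- max(w)
    keep[i] <- maxw[i] >= drop_threshold
  }
  grid <- grid[keep, , drop = FALSE]
  rownames(grid) <- NULL

  # full continuous window mass in px^2: dA = (ppd * e)^2 du dtheta
  radial_c <- stats::integrate(function(x) .bump(x, de) * exp(2 * x),
                               -de, de, rel.tol = 1e-10)$value
  ang_c <- dth      # integral of the squared-cosine bump over its support
  mass_total <- px_per_deg^2 * exp(2 * grid$u) * radial_c * ang_c

  centers <- data.frame(u = grid$u, ecc_deg = exp(grid$u),
                        angle_rad = grid$angle, mass_total = mass_total)
  structure(list(centers = centers, n_windows = nrow(centers),
                 field_px = n, px_per_deg = px_per_deg, fixation = fixation,
                 s = s, delta_e = de, delta_theta = dth, n_theta = ntheta,
                 u_map = u_map, angle_map = angle_map),
            class = "poolgeom")
}

print.poolgeom <- function(x, ...) {
  cat(sprintf(
    "pooling geometry: s = %.3g, %d windows over %d x %d px (%.3g px/deg)\n",
    x$s, x$n_windows, x$field_px, x$field_px, x$px_per_deg))
  cat(sprintf("  eccentricity range %.2f..%.2f deg, %d angular sectors\n",
              min(exp(x$u_map)), max(exp(x$u_map)), x$n_theta))
  invisible(x)
}

#' Evaluate pooling window weight maps
#'
#' Returns the weight maps of the selected windows as a dense matrix with
#' one row per window (row-major over the field matrix columns, i.e.
#' `as.vector(map)`).
#'
#' @param geom a `poolgeom` object.
#' @param idx window indices (default all).
#' @return `length(idx)` x `field_px^2` matrix.
#' @export
window_weights <- function(geom, idx = seq_len(geom$n_windows)) {
  n <- geom$field_px
  W <- matrix(0, length(idx), n * n)
  for (r in seq_along(idx)) {
    i <- idx[r]
    wu <- .bump(geom$u_map - geom$centers$u[i], geom$delta_e)
    dthw <- ((geom$angle_map - geom$centers$angle_rad[i] + pi) %% (2 * pi)) - pi
    W[r, ] <- as.vector(wu * .bump(dthw, geom$delta_theta))
  }
  W
}

#' Pointwise sum of all pooling windows
#'
#' Accumulates the window weight maps over the field; by construction the
#' result is 1 at every pixel (partition of unity), up to floating-point
#' error and the mass of any dropped windows.
#'
#' @param geom a `poolgeom` object.
#' @return `field_px` x `field_px` matrix of window sums.
#' @export
window_sum <- function(geom) {
  n <- geom$field_px
  acc <- matrix(0, n, n)
  for (i in seq_len(geom$n_windows)) {
    wu <- .bump(geom$u_map - geom$centers$u[i], geom$delta_e)
    dthw <- ((geom$angle_map - geom$centers$angle_rad[i] + pi) %% (2 * pi)) - pi
    acc <- acc + wu * .bump(dthw, geom$delta_theta)
  }
  acc
}

#' Radial full-width at half maximum of a window
#'
#' Measured in degrees along the radial direction through the window
#' center; equals `s * eccentricity` for the squared-cosine profile.
#'
#' @param geom a `poolgeom` object.
#' @param idx window index.
#' @return FWHM in degrees.
#' @export
window_radial_fwhm <- function(geom, idx) {
  u0 <- geom$centers$u[idx]
  exp(u0 + geom$delta_e / 2) - exp(u0 - geom$delta_e / 2)
}
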