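## Pairwise-product texture statistics measured on steerable-pyramid
## responses: spatial covariances of linear and magnitude responses within a
## local neighborhood, cross-orientation and cross-scale magnitude
## covariances, and cross-scale products of linear responses with
## phase-doubled coarser responses.  Statistics can be computed globally
## (spatial means over the whole image) or as weighted averages under an
## arbitrary nonnegative weight map; the two agree exactly for a uniform
## weight.

# unique spatial offsets of an nb x nb neighborhood under point symmetry:
# (0,0),(0,1)..(0,h), then dy=1..h x dx=-h..h  -> (nb^2-1)/2 + 1 offsets
.offsets <- function(neighborhood) {
  h <- (neighborhood - 1L) %/% 2L
  off <- rbind(cbind(0L, 0L:h),
               do.call(rbind, lapply(seq_len(h), function(dy) cbind(dy, -h:h))))
  colnames(off) <- c("dy", "dx")
  off
}

.n_offsets <- function(neighborhood) (neighborhood^2 - 1L) %/% 2L + 1L

#' Catalog of observer summary statistics
#'
#' Enumerates, in a fixed deterministic order, the pairwise-product
#' statistics used by the pooling observer: spatial covariances of linear
#' responses (per scale) and of magnitude responses (per band) over the
#' unique offsets of an odd neighborhood; cross-scale and
#' cross-orientation magnitude covariances; and real/imaginary parts of
#' cross-scale products of linear responses with phase-doubled coarser
#' responses.  For 4 scales, 4 orientations and a 7x7 neighborhood the
#' group sizes are 100, 400, 48, 24 and 96, totalling 668.
#'
#' @param n_scales number of pyramid scales K.
#' @param n_orientations number of orientations O.
#' @param neighborhood odd integer, spatial neighborhood width.
#' @return data.frame with columns `group`, `scale`, `scale2`, `ori`,
#'   `ori2`, `dy`, `dx`, `component` and row names giving stable ids.
#' @export
statistic_catalog <- function(n_scales = 4L, n_orientations = 4L, neighborhood = 7L) {
  if (neighborhood %% 2L != 1L || neighborhood < 1L)
    stop("`neighborhood` must be an odd positive integer")
  K <- as.integer(n_scales); O <- as.integer(n_orientations)
  off <- .offsets(neighborhood)
  no <- nrow(off)
  rows <- list()
  add <- function(group, scale, scale2, ori, ori2, dy, dx, component) {
    rows[[length(rows) + 1L]] <<- data.frame(
      group = group, scale = scale, scale2 = scale2, ori = ori, ori2 = ori2,
      dy = dy, dx = dx, component = component, stringsAsFactors = FALSE)
  }
  for (k in 1:K)
    add("linear_cross_position", k, NA_integer_, NA_integer_, NA_integer_,
        off[, 1], off[, 2], "n/a")
  for (k in 1:K) for (o in 1:O)
    add("magnitude_cross_position", k, NA_integer_, o, NA_integer_,
        off[, 1], off[, 2], "n/a")
  for (k in 1:(K - 1)) for (of in 1:O) for (oc in 1:O)
    add("magnitude_cross_scale", k, k + 1L, of, oc, NA_integer_, NA_integer_, "n/a")
  for (k in 1:K) for (o1 in 1:(O - 1)) for (o2 in (o1 + 1):O)
    add("magnitude_cross_orientation", k, NA_integer_, o1, o2,
        NA_integer_, NA_integer_, "n/a")
  for (k in 1:(K - 1)) for (of in 1:O) for (oc in 1:O) for (comp in c("real", "imag"))
    add("linear_phase_cross_scale", k, k + 1L, of, oc, NA_integer_, NA_integer_, comp)
  cat <- do.call(rbind, rows)
  rownames(cat) <- .stat_ids(cat)
  cat
}

.stat_ids <- function(cat) {
  id <- paste0(
    c(linear_cross_position = "lin", magnitude_cross_position = "mag",
      magnitude_cross_scale = "mcs", magnitude_cross_orientation = "mco",
      linear_phase_cross_scale = "phs", band_mean_magnitude = "bmm",
      marginal = "mar")[cat$group],
    "_s", cat$scale,
    ifelse(is.na(cat$scale2), "", paste0("x", cat$scale2)),
    ifelse(is.na(cat$ori), "", paste0("_o", cat$ori)),
    ifelse(is.na(cat$ori2), "", paste0("x", cat$ori2)),
    ifelse(is.na(cat$dy), "", paste0("_d", cat$dy, ".", cat$dx)),
    ifelse(cat$component %in% c("real", "imag"), paste0("_", cat$component), ""))
  id[cat$group == "marginal"] <- paste0("mar_", cat$component[cat$group == "marginal"])
  id
}

# circular shift: out[i,j] = q[i+dy, j+dx]
.cshift <- function(q, dy, dx) {
  n <- nrow(q); m <- ncol(q)
  q[(((seq_len(n) - 1L) + dy) %% n) + 1L, (((seq_len(m) - 1L) + dx) %% m) + 1L,
    drop = FALSE]
}

# derived response maps per scale: partial lowpass image, magnitudes,
# upsampled next-coarser magnitudes, and phase-doubled upsampled
# next-coarser complex bands
.stat_maps <- function(coeffs) {
  K <- coeffs$n_scales; O <- coeffs$n_orientations
  mags <- magnitude_responses(coeffs)
  mu <- vector("list", K - 1L)
  for (k in seq_len(K - 1L))
    mu[[k]] <- lapply(mags[[k + 1L]], .upsample2_real)
  pu <- if (K >= 2L) phase_doubled_responses(coeffs) else list()
  list(p = coeffs$plow, mags = mags, mu = mu, pu = pu,
       bands = coeffs$bands, K = K, O = O)
}

# weighted spatial covariance machinery for a single weight map per scale.
# wlist[[k]] is a nonnegative matrix at the scale-k resolution (or NULL for
# uniform weights); values are weighted means Sum(w*map)/Sum(w).
.wmean <- function(map, w) if (is.null(w)) mean(map) else sum(w * map) / sum(w)

# observer statistic values given response maps and per-scale weights
.observer_values <- function(maps, wlist, neighborhood) {
  K <- maps$K; O <- maps$O
  off <- .offsets(neighborhood)
  no <- nrow(off)
  wk <- function(k) if (is.null(wlist)) NULL else wlist[[k]]

  lin <- numeric(0)
  for (k in 1:K) {
    q <- maps$p[[k]]; w <- wk(k)
    mq <- .wmean(q, w)
    v <- vapply(seq_len(no), function(i) {
      s <- .cshift(q, off[i, 1], off[i, 2])
      .wmean(q * s, w) - mq * .wmean(s, w)
    }, numeric(1))
    lin <- c(lin, v)
  }

  magp <- numeric(0)
  for (k in 1:K) for (o in 1:O) {
    q <- maps$mags[[k]][[o]]; w <- wk(k)
    mq <- .wmean(q, w)
    v <- vapply(seq_len(no), function(i) {
      s <- .cshift(q, off[i, 1], off[i, 2])
      .wmean(q * s, w) - mq * .wmean(s, w)
    }, numeric(1))
    magp <- c(magp, v)
  }

  mcs <- numeric(0)
  for (k in seq_len(K - 1)) for (of in 1:O) for (oc in 1:O) {
    f <- maps$mags[[k]][[of]]; c2 <- maps$mu[[k]][[oc]]; w <- wk(k)
    mcs <- c(mcs, .wmean(f * c2, w) - .wmean(f, w) * .wmean(c2, w))
  }

  mco <- numeric(0)
  for (k in 1:K) for (o1 in 1:(O - 1)) for (o2 in (o1 + 1):O) {
    a <- maps$mags[[k]][[o1]]; b <- maps$mags[[k]][[o2]]; w <- wk(k)
    mco <- c(mco, .wmean(a * b, w) - .wmean(a, w) * .wmean(b, w))
  }

  phs <- numeric(0)
  for (k in seq_len(K - 1)) for (of in 1:O) for (oc in 1:O) {
    pr <- maps$bands[[k]][[of]] * Conj(maps$pu[[k]][[oc]])
    w <- wk(k)
    phs <- c(phs, .wmean(Re(pr), w), .wmean(Im(pr), w))
  }

  c(lin, magp, mcs, mco, phs)
}

.new_texstats <- function(values, labels, K, O, neighborhood, degenerate = FALSE) {
  names(values) <- rownames(labels)
  structure(list(values = values, labels = labels, n_scales = K,
                 n_orientations = O, neighborhood = neighborhood,
                 degenerate = degenerate),
            class = "texstats")
}

print.texstats <- function(x, ...) {
  cat(sprintf("texture statistics: %d values (%d groups), K=%d O=%d nb=%d\n",
              length(x$values), length(unique(x$labels$group)),
              x$n_scales, x$n_orientations, x$neighborhood))
  invisible(x)
}

# full label table: observer catalog + band mean magnitudes + marginals
.full_labels <- function(K, O, neighborhood) {
  lab_bmm <- expand.grid(ori = 1:O, scale = 1:K)[, c("scale", "ori")]
  lab_bmm <- data.frame(
    group = "band_mean_magnitude", scale = lab_bmm$scale, scale2 = NA_integer_,
    ori = lab_bmm$ori, ori2 = NA_integer_, dy = NA_integer_, dx = NA_integer_,
    component = "n/a", stringsAsFactors = FALSE)
  lab_marg <- data.frame(
    group = "marginal", scale = NA_integer_, scale2 = NA_integer_,
    ori = NA_integer_, ori2 = NA_integer_, dy = NA_integer_, dx = NA_integer_,
    component = c("mean", "var", "skew", "kurtosis"), stringsAsFactors = FALSE)
  labels <- rbind(statistic_catalog(K, O, neighborhood), lab_bmm, lab_marg)
  rownames(labels) <- .stat_ids(labels)
  labels
}

#' Full texture statistic vector of an image
#'
#' Computes the observer statistic set (see [statistic_catalog()]) over the
#' full spatial extent of the image, plus the mean magnitude of each
#' oriented band and the marginal pixel statistics (mean, variance, skew,
#' and kurtosis in the `m4/m2^2` convention, Gaussian = 3).  This is the
#' statistic vector that defines a texture family and serves as the
#' synthesis target.
#'
#' For a constant (zero-variance) image the skew and kurtosis are
#' undefined; they are returned as `NaN` and the result is flagged
#' `degenerate` rather than raising an error.
#'
#' @param image numeric square matrix.
#' @inheritParams statistic_catalog
#' @return a `texstats` object (values + label table).
#' @export
full_statistics <- function(image, n_scales = 4L, n_orientations = 4L,
                            neighborhood = 7L) {
  pyr <- build_pyramid(image, n_scales, n_orientations)
  K <- pyr$n_scales; O <- pyr$n_orientations
  maps <- .stat_maps(pyr)
  obs <- .observer_values(maps, NULL, neighborhood)

  bmm <- numeric(0)
  for (k in 1:K) for (o in 1:O)
    bmm <- c(bmm, mean(maps$mags[[k]][[o]]))

  mu <- mean(image)
  m2 <- mean((image - mu)^2)
  degenerate <- m2 <= 0
  skew <- if (degenerate) NaN else mean((image - mu)^3) / m2^1.5
  kurt <- if (degenerate) NaN else mean((image - mu)^4) / m2^2
  marg <- c(mu, m2, skew, kurt)
  labels <- .full_labels(K, O, neighborhood)
  .new_texstats(c(obs, bmm, marg), labels, K, O, neighborhood, degenerate)
}

#' Observer subset of a statistic vector
#'
#' Drops the band mean magnitudes and marginal pixel statistics, keeping
#' the covariance-type statistics used by the pooling observer (668 for
#' the default configuration).
#'
#' @param x a `texstats` object.
#' @return a `texstats` object restricted to the observer groups.
#' @export
observer_subset <- function(x) {
  stopifnot(inherits(x, "texstats"))
  keep <- !(x$labels$group %in% c("band_mean_magnitude", "marginal"))
  .new_texstats(x$values[keep], x$labels[keep, , drop = FALSE],
                x$n_scales, x$n_orientations, x$neighborhood, x$degenerate)
}

# block-average a matrix by an integer factor (area-preserving resampling
# of weight maps to coarser band resolutions)
.block_mean <- function(w, f) {
  if (f == 1L) return(w)
  n <- nrow(w)
  stopifnot(n %% f == 0L)
  m <- n %/% f
  # average f x f blocks
  w1 <- matrix(colSums(matrix(w, f, m * n)), m, n)       # collapse rows
  t(matrix(colSums(matrix(t(w1), f, m * m)), m, m)) / f^2 # collapse cols
}

# per-scale weight maps from a full-resolution weight map
.weight_pyramid <- function(weight, n_scales) {
  lapply(seq_len(n_scales), function(k) .block_mean(weight, 2L^(k - 1L)))
}

#' Weighted (pooled) observer statistics
#'
#' Computes the observer statistic set as spatially weighted averages under
#' a nonnegative weight map: every pairwise product is averaged as
#' `sum(w * product) / sum(w)`, with the weight map block-averaged to each
#' band's resolution and covariance means subtracted within the weighted
#' region.  With a uniform weight this reproduces the observer subset of
#' [full_statistics()] exactly.
#'
#' @param coeffs a `texpyr` object.
#' @param weight nonnegative numeric matrix at the source resolution (a
#'   pooling window), with positive total mass.
#' @inheritParams statistic_catalog
#' @return a `texstats` object of length 668 (default configuration).
#' @export
observer_statistics <- function(coeffs, weight, neighborhood = 7L) {
  .check_pyr(coeffs)
  n <- coeffs$source_shape[1]
  if (!is.matrix(weight) || nrow(weight) != n || ncol(weight) != n)
    stop("`weight` must match the pyramid source shape")
  if (any(weight < 0)) stop("`weight` must be nonnegative")
  if (sum(weight) <= 0) stop("`weight` must have positive mass")
  maps <- .stat_maps(coeffs)
  wlist <- .weight_pyramid(weight, coeffs$n_scales)
  vals <- .observer_values(maps, wlist, neighborhood)
  labels <- statistic_catalog(coeffs$n_scales, coeffs$n_orientations, neighborhood)
  .new_texstats(vals, labels, coeffs$n_scales, coeffs$n_orientations, neighborhood)
}

#' Coefficient of variation across statistic vectors
#'
#' For a list of statistic vectors sharing one catalog (e.g. measured from
#' different samples of a texture family), computes per statistic the
#' standard deviation across vectors (n-1 denominator) divided by the mean
#' across vectors.  Entries whose absolute mean falls below a floor of
#' `mean_floor` times the median absolute mean of their statistic group are
#' flagged and excluded (`cv = NA`), since the ratio is then meaningless.
#'
#' @param stat_vectors list of at least two `texstats` objects with
#'   identical catalogs.
#' @param mean_floor relative floor for the across-sample mean (default
#'   1e-8).
#' @return data.frame: the label columns plus `mean`, `sd`, `cv`,
#'   `flagged`.
#' @export
coefficient_of_variation <- function(stat_vectors, mean_floor = 1e-8) {
  if (length(stat_vectors) < 2L)
    stop("need at least 2 statistic vectors")
  ids <- lapply(stat_vectors, function(s) rownames(s$labels))
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]])))
    stop("statistic vectors have mismatched catalogs")
  V <- vapply(stat_vectors, function(s) s$values,
              numeric(length(stat_vectors[[1]]$values)))
  m <- rowMeans(V)
  s <- apply(V, 1, stats::sd)
  lab <- stat_vectors[[1]]$labels
  floor_by_group <- stats::ave(abs(m), lab$group,
                               FUN = function(z) stats::median(z))
  flagged <- abs(m) < mean_floor * floor_by_group
  cv <- ifelse(flagged, NA_real_, s / m)
  cbind(lab, data.frame(mean = m, sd = s, cv = cv, flagged = flagged))
}

#' Write / read a statistic vector as tab-separated text
#'
#' Serializes the label table plus values in the catalog order, so that
#' stored vectors can be compared across versions.
#'
#' @param x a `texstats` object.
#' @param path file path.
#' @return `write_statistics` returns `path` invisibly; `read_statistics`
#'   the data.frame.
#' @export
write_statistics <- function(x, path) {
  stopifnot(inherits(x, "texstats"))
  df <- cbind(id = rownames(x$labels), x$labels, value = unname(x$values))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_statistics
#' @export
read_statistics <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
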