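## Internal loss/gradient engine for texture synthesis.
##
## The loss is a sum over statistic groups of squared deviations from the
## target, each group divided by its squared target norm.  The forward pass
## recomputes exactly the statistics of full_statistics() but organized for
## speed: autocorrelations via FFT, and cross-scale products evaluated at
## the coarse resolution through the adjoint identity
##   mean_fine(f * upsample(u)) = mean_coarse(downsample_adj(f) * u),
## which is exact for the frequency-domain up/down sampling pair used here.
## The backward pass propagates analytic gradients through magnitudes,
## phase doubling and the pyramid (the adjoint of the decimated analysis
## operator is the reconstruction with per-level weights 4^(1-k)).

# plain central index crop (no value rescaling): adjoint of .spec_pad / 4
.spec_crop_idx <- function(M) {
  n <- nrow(M)
  idx <- c(1:(n / 4), (n - n / 4 + 1):n)
  M[idx, idx]
}

# plain zero-pad at the same indices (no x4): adjoint of .spec_crop_idx
.spec_pad_idx <- function(M) {
  n <- nrow(M)
  out <- matrix(0 + 0i, 2 * n, 2 * n)
  idx <- c(1:(n / 2), (2 * n - n / 2 + 1):(2 * n))
  out[idx, idx] <- M
  out
}

# linear matrix indices of the offset entries of an FFT-layout
# autocorrelation map, and of the +/-d kernel positions
.offset_index <- function(n, off) {
  r <- (off[, 1] %% n) + 1L
  c <- (off[, 2] %% n) + 1L
  (c - 1L) * n + r
}

.synth_plan <- function(target, size_px) {
  stopifnot(inherits(target, "texstats"))
  K <- target$n_scales; O <- target$n_orientations; nb <- target$neighborhood
  if (size_px %% 2^K != 0)
    stop("`size_px` must be divisible by 2^n_scales")
  off <- .offsets(nb)
  lab <- target$labels
  groups <- unique(lab$group)
  gidx <- lapply(groups, function(g) which(lab$group == g))
  names(gidx) <- groups
  tval <- unname(target$values)
  # group norms; near-zero-norm groups (e.g. phase statistics of a
  # noise-like target) are measured against a floor of 1% of the largest
  # group norm, so the relative gate stays attainable for them
  tnorm <- vapply(gidx, function(i) sqrt(sum(tval[i]^2)), numeric(1))
  gfloor <- max(1e-2 * max(tnorm), 1e-10)
  gden <- pmax(tnorm^2, gfloor^2)
  # per-scale offset index vectors (+d and -d) at each band resolution
  oidx <- lapply(1:K, function(k) {
    nk <- size_px / 2^(k - 1)
    list(pos = .offset_index(nk, off),
         neg = .offset_index(nk, -off))
  })
  # contiguous group ranges (0-based) and frequency masks for the compiled
  # evaluation path
  gstart <- vapply(gidx, min, numeric(1)) - 1L
  gend <- vapply(gidx, max, numeric(1)) - 1L
  stopifnot(all(gend - gstart + 1L == lengths(gidx)))
  masks <- lapply(1:K, function(k) {
    mk <- .level_masks(size_px / 2^(k - 1), O)
    list(lo = mk$lo, hi = mk$hi, ang = mk$ang)
  })
  m0 <- .level_masks(size_px, O)
  masks[[K + 1L]] <- list(lo0 = m0$lo0, hi0 = m0$hi0)
  list(K = K, O = O, nb = nb, n = size_px, off = off, noff = nrow(off),
       target = tval, labels = lab, groups = groups, gidx = gidx, gden = gden,
       gfloor = gfloor,
       gstart = as.integer(gstart), gend = as.integer(gend), masks = masks)
}

# compiled forward+backward pass (see src/synth_eval.cpp); the plain-R
# implementation below is retained as its cross-validation oracle
.synth_eval_fast <- function(x, plan) {
  res <- .synth_eval_cpp(x, plan$masks, plan$off, plan$target,
                         plan$gstart, plan$gend, plan$gden, plan$gfloor,
                         plan$K, plan$O)
  res$group_err <- stats::setNames(as.vector(res$group_err), plan$groups)
  res$stats <- as.vector(res$stats)
  res
}

# forward + backward in one pass; returns loss, gradient image, statistic
# vector and per-group relative errors
.synth_eval <- function(x, plan) {
  K <- plan$K; O <- plan$O; n <- plan$n
  off <- plan$off; noff <- plan$noff
  m0 <- .level_masks(n, O)

  ## ---- forward pyramid, keeping spectra ----
  X <- stats::fft(x)
  S <- vector("list", K + 1L)       # lowpass spectra entering each level
  S[[1L]] <- m0$lo0 * X
  Bs <- vector("list", K)           # band spectra
  bsp <- vector("list", K)          # band spatial (complex)
  msp <- vector("list", K)          # magnitudes
  Mh <- vector("list", K)           # fft of magnitudes
  mk_list <- vector("list", K)
  for (k in 1:K) {
    nk <- n / 2^(k - 1)
    mk <- .level_masks(nk, O); mk_list[[k]] <- mk
    HS <- mk$hi * S[[k]]
    Bs[[k]] <- lapply(1:O, function(o) mk$ang[[o]] * HS)
    bsp[[k]] <- lapply(Bs[[k]], .ifft2)
    msp[[k]] <- lapply(bsp[[k]], Mod)
    Mh[[k]] <- lapply(msp[[k]], stats::fft)
    S[[k + 1L]] <- .spec_crop(mk$lo * S[[k]])
  }

  ## derived cross-scale maps at coarse resolutions
  dmf <- vector("list", K - 1L)  # Re(downsample_adj(m_fine)) at coarse res
  dbf <- vector("list", K - 1L)  # downsample_adj(b_fine), complex
  pdc <- vector("list", K - 1L)  # phase-doubled coarse bands (native res)
  if (K >= 2L) for (k in 1:(K - 1L)) {
    dmf[[k]] <- lapply(1:O, function(o) Re(.ifft2(.spec_crop_idx(Mh[[k]][[o]]))))
    dbf[[k]] <- lapply(1:O, function(o) .ifft2(.spec_crop_idx(Bs[[k]][[o]])))
    pdc[[k]] <- lapply(1:O, function(o) {
      b <- bsp[[k + 1L]][[o]]; m <- msp[[k + 1L]][[o]]
      pd <- b; nz <- m > 0
      pd[nz] <- b[nz]^2 / m[nz]; pd[!nz] <- 0
      pd
    })
  }

  mu_p <- vapply(1:K, function(k) Re(S[[k]][1, 1]) / (n / 2^(k - 1))^2, numeric(1))
  mu_m <- lapply(1:K, function(k) vapply(msp[[k]], mean, numeric(1)))

  ## ---- statistics (same order as full_statistics) ----
  # autocorrelation maps once per map
  acsel <- function(Q, nk, mu, oi) {
    ac <- Re(.ifft2(Mod(Q)^2)) / nk^2
    ac[oi] - mu^2
  }
  oi_list <- lapply(1:K, function(k) .offset_index(n / 2^(k - 1), off))

  lin <- unlist(lapply(1:K, function(k)
    acsel(S[[k]], n / 2^(k - 1), mu_p[k], oi_list[[k]])))
  magp <- unlist(lapply(1:K, function(k)
    unlist(lapply(1:O, function(o)
      acsel(Mh[[k]][[o]], n / 2^(k - 1), mu_m[[k]][o], oi_list[[k]])))))

  mcs <- numeric(0)
  if (K >= 2L) for (k in 1:(K - 1L)) {
    Nf <- (n / 2^(k - 1))^2
    for (of in 1:O) for (oc in 1:O)
      mcs <- c(mcs, sum(dmf[[k]][[of]] * msp[[k + 1L]][[oc]]) / Nf -
                 mu_m[[k]][of] * mu_m[[k + 1L]][oc])
  }

  mco <- numeric(0)
  for (k in 1:K) {
    Nk <- (n / 2^(k - 1))^2
    for (o1 in 1:(O - 1)) for (o2 in (o1 + 1):O)
      mco <- c(mco, sum(msp[[k]][[o1]] * msp[[k]][[o2]]) / Nk -
                 mu_m[[k]][o1] * mu_m[[k]][o2])
  }

  phs <- numeric(0)
  if (K >= 2L) for (k in 1:(K - 1L)) {
    Nf <- (n / 2^(k - 1))^2
    for (of in 1:O) for (oc in 1:O) {
      z <- sum(dbf[[k]][[of]] * Conj(pdc[[k]][[oc]])) / Nf
      phs <- c(phs, Re(z), Im(z))
    }
  }

  bmm <- unlist(mu_m)

  mu <- mean(x)
  xc <- x - mu
  m2 <- mean(xc^2); m3 <- mean(xc^3); m4 <- mean(xc^4)
  marg <- c(mu, m2, m3 / m2^1.5, m4 / m2^2)

  s <- c(lin, magp, mcs, mco, phs, bmm, marg)

  ## ---- loss and per-statistic error signal ----
  t <- plan$target
  d <- s - t
  loss <- 0
  e <- numeric(length(s))
  gerr <- numeric(length(plan$groups)); names(gerr) <- plan$groups
  for (gi in seq_along(plan$groups)) {
    idx <- plan$gidx[[gi]]
    loss <- loss + sum(d[idx]^2) / plan$gden[gi]
    e[idx] <- 2 * d[idx] / plan$gden[gi]
    gerr[gi] <- sqrt(sum(d[idx]^2)) / (sqrt(sum(t[idx]^2)) + plan$gfloor)
  }

  ## ---- backward ----
  # split error signal back into blocks, same construction order
  pos <- 0L
  take <- function(len) {
    out <- e[(pos + 1L):(pos + len)]; pos <<- pos + len; out
  }
  e_lin <- matrix(take(K * noff), noff, K)
  e_mag <- array(take(K * O * noff), c(noff, O, K))
  e_mcs <- if (K >= 2L) array(take((K - 1) * O * O), c(O, O, K - 1L)) else NULL # [oc, of, k]
  e_mco <- take(K * choose(O, 2))
  e_phs <- if (K >= 2L) array(take((K - 1) * O * O * 2), c(2, O, O, K - 1L)) else NULL
  e_bmm <- matrix(take(K * O), O, K)
  e_mar <- take(4L)

  # kernel image for the autocorrelation gradient convolution
  acker <- function(nk, ev, oi) {
    kern <- numeric(nk * nk)
    pos_i <- .offset_index(nk, plan$off)
    neg_i <- .offset_index(nk, -plan$off)
    for (i in seq_len(noff)) {
      kern[pos_i[i]] <- kern[pos_i[i]] + ev[i]
      kern[neg_i[i]] <- kern[neg_i[i]] + ev[i]
    }
    matrix(kern, nk, nk)
  }

  # band-spectrum gradient accumulators (frequency domain) and magnitude
  # gradient accumulators
  Gb_freq <- lapply(1:K, function(k) {
    nk <- n / 2^(k - 1)
    lapply(1:O, function(o) matrix(0 + 0i, nk, nk))
  })
  gm_sp <- lapply(1:K, function(k) {
    nk <- n / 2^(k - 1)
    lapply(1:O, function(o) matrix(0, nk, nk))
  })
  gm_freq <- lapply(1:K, function(k) {
    nk <- n / 2^(k - 1)
    lapply(1:O, function(o) matrix(0 + 0i, nk, nk))
  })
  gb_sp <- lapply(1:K, function(k) {
    nk <- n / 2^(k - 1)
    lapply(1:O, function(o) matrix(0 + 0i, nk, nk))
  })

  # magnitude autocorrelation + cross-orientation + band means
  ico <- 0L
  for (k in 1:K) {
    nk <- n / 2^(k - 1); Nk <- nk^2
    for (o in 1:O) {
      ev <- e_mag[, o, k]
      if (any(ev != 0)) {
        kf <- stats::fft(acker(nk, ev, NULL))
        gm_freq[[k]][[o]] <- gm_freq[[k]][[o]] + Mh[[k]][[o]] * kf / Nk
        gm_sp[[k]][[o]] <- gm_sp[[k]][[o]] - 2 * mu_m[[k]][o] * sum(ev) / Nk
      }
      gm_sp[[k]][[o]] <- gm_sp[[k]][[o]] + e_bmm[o, k] / Nk
    }
    for (o1 in 1:(O - 1)) for (o2 in (o1 + 1):O) {
      ico <- ico + 1L
      ev <- e_mco[ico]
      if (ev != 0) {
        gm_sp[[k]][[o1]] <- gm_sp[[k]][[o1]] +
          ev * (msp[[k]][[o2]] - mu_m[[k]][o2]) / Nk
        gm_sp[[k]][[o2]] <- gm_sp[[k]][[o2]] +
          ev * (msp[[k]][[o1]] - mu_m[[k]][o1]) / Nk
      }
    }
  }

  # cross-scale magnitude and phase terms
  if (K >= 2L) for (k in 1:(K - 1L)) {
    nf <- n / 2^(k - 1); Nf <- nf^2; Nc <- (nf / 2)^2
    for (of in 1:O) {
      gc_m <- matrix(0, nf / 2, nf / 2)   # -> fft -> pad into fine magnitude
      gc_b <- matrix(0 + 0i, nf / 2, nf / 2)
      for (oc in 1:O) {
        ev <- e_mcs[oc, of, k]
        if (ev != 0) {
          # coarse side
          gm_sp[[k + 1L]][[oc]] <- gm_sp[[k + 1L]][[oc]] +
            ev * (dmf[[k]][[of]] / Nf - mu_m[[k]][of] / Nc)
          # fine side: mean correction + upsampled product term
          gm_sp[[k]][[of]] <- gm_sp[[k]][[of]] - ev * mu_m[[k + 1L]][oc] / Nf
          gc_m <- gc_m + ev * msp[[k + 1L]][[oc]] / Nf
        }
        er <- e_phs[1, oc, of, k]; ei <- e_phs[2, oc, of, k]
        if (er != 0 || ei != 0) {
          ez <- complex(real = er, imaginary = ei)
          gc_b <- gc_b + ez * pdc[[k]][[oc]] / Nf
          # phase-doubling adjoint onto the coarse band
          gpd <- Conj(ez) * dbf[[k]][[of]] / Nf
          b <- bsp[[k + 1L]][[oc]]; m <- msp[[k + 1L]][[oc]]
          nz <- m > 0
          eiθ <- b
          eiθ[nz] <- b[nz] / m[nz]; eiθ[!nz] <- 0
          gb_sp[[k + 1L]][[oc]] <- gb_sp[[k + 1L]][[oc]] +
            1.5 * Conj(eiθ) * gpd - 0.5 * eiθ^3 * Conj(gpd)
        }
      }
      # adjoint of the index crop carries the fine/coarse pixel-count ratio
      if (any(gc_m != 0))
        gm_freq[[k]][[of]] <- gm_freq[[k]][[of]] + 4 * .spec_pad_idx(stats::fft(gc_m))
      if (any(gc_b != 0))
        Gb_freq[[k]][[of]] <- Gb_freq[[k]][[of]] + 4 * .spec_pad_idx(stats::fft(gc_b))
    }
  }

  ## adjoint pyramid recursion
  Sadj <- matrix(0 + 0i, n / 2^K, n / 2^K)   # no direct lowpass gradient
  for (k in K:1) {
    nk <- n / 2^(k - 1); Nk <- nk^2
    mk <- mk_list[[k]]
    Sadj <- mk$lo * .spec_pad(Sadj)
    w <- 4^(1 - k)
    Tacc <- matrix(0 + 0i, nk, nk)
    for (o in 1:O) {
      # assemble spatial band gradient: magnitude chain + direct complex parts
      gm <- Re(.ifft2(gm_freq[[k]][[o]])) + gm_sp[[k]][[o]]
      b <- bsp[[k]][[o]]; m <- msp[[k]][[o]]
      gb <- gb_sp[[k]][[o]]
      nz <- m > 0
      gb[nz] <- gb[nz] + gm[nz] * b[nz] / m[nz]
      Gf <- stats::fft(gb) + Gb_freq[[k]][[o]]
      Tacc <- Tacc + mk$ang[[o]] * Gf
    }
    Tacc <- mk$hi * Tacc * w
    Sadj <- Sadj + (Tacc + Conj(.flip_freq(Tacc))) / 2
    # linear cross-position gradient enters as a spectrum contribution
    ev <- e_lin[, k]
    if (any(ev != 0)) {
      kf <- stats::fft(acker(nk, ev, NULL))
      Gp <- S[[k]] * kf / Nk
      Gp[1, 1] <- Gp[1, 1] - 2 * mu_p[k] * sum(ev) / Nk * Nk  # constant map
      Sadj <- Sadj + Gp * w
    }
  }
  gx <- Re(.ifft2(m0$lo0 * Sadj))

  # marginal gradients (direct pixel terms)
  N <- n^2
  if (any(e_mar != 0)) {
    gx <- gx + e_mar[1] / N
    d2 <- 2 * xc / N
    d3 <- (3 / N) * (xc^2 - m2)
    d4 <- (4 / N) * (xc^3 - m3)
    gx <- gx + e_mar[2] * d2
    if (m2 > 0) {
      gx <- gx + e_mar[3] * (d3 / m2^1.5 - 1.5 * m3 / m2^2.5 * d2)
      gx <- gx + e_mar[4] * (d4 / m2^2 - 2 * m4 / m2^3 * d2)
    }
  }

  list(loss = loss, grad = gx, stats = s, group_err = gerr)
}
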