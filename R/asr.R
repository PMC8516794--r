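#' Calibrate an artifact subspace reconstruction model
#'
#' Learns the clean-data statistics used by [asr_apply()]: the principal axes
#' (eigenvector basis) of the calibration covariance, and a per-component RMS
#' threshold equal to the mean plus `cutoff_k` standard deviations of the
#' windowed component RMS over sliding windows.
#'
#' @param calib Channels x samples matrix of clean (calibration) data; at
#'   least 30 s.
#' @param rate_hz Sampling rate (Hz).
#' @param cutoff_k Burst criterion: SD multiplier on the component RMS
#'   distribution (default 20).
#' @param window_s Sliding-window length (s).
#' @param labels Optional channel labels stored for the channel-set check.
#' @return A list of class `asr_model` with `mixing` (eigenvectors, columns),
#'   `thresholds`, `center`, `cov`, `cutoff_k`, `window_s`, `rate_hz`,
#'   `labels`.
#' @export
asr_calibrate <- function(calib, rate_hz, cutoff_k = 20, window_s = 0.5,
                          labels = rownames(calib)) {
  stopifnot(is.matrix(calib))
  if (ncol(calib) < 30 * rate_hz) {
    abort("calibration segment must be at least 30 s long.")
  }
  center <- rowMeans(calib)
  xc <- calib - center
  C <- xc %*% t(xc) / ncol(xc)
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values)) {
    # name the channels most aligned with the null directions
    null_dir <- eg$vectors[, which.min(eg$values)]
    worst <- order(abs(null_dir), decreasing = TRUE)[1:2]
    nm <- if (!is.null(labels)) labels[worst] else as.character(worst)
    abort(sprintf("rank-deficient calibration covariance (channels %s).",
                  paste(nm, collapse = ", ")))
  }
  V <- eg$vectors
  y <- t(V) %*% xc
  w <- round(window_s * rate_hz)
  starts <- seq(1, ncol(y) - w + 1, by = max(1, floor(w / 2)))
  rms <- vapply(starts, function(s) {
    sqrt(rowMeans(y[, s:(s + w - 1), drop = FALSE]^2))
  }, numeric(nrow(y)))
  if (is.null(dim(rms))) rms <- matrix(rms, nrow = nrow(y))
  thr <- rowMeans(rms) + cutoff_k * apply(rms, 1, sd)
  structure(
    list(mixing = V, thresholds = thr, center = center, cov = C,
         cutoff_k = cutoff_k, window_s = window_s, rate_hz = rate_hz,
         labels = labels),
    class = "asr_model"
  )
}

#' Apply artifact subspace reconstruction
#'
#' Sliding-window subspace correction: each window's covariance is
#' eigendecomposed, the calibration threshold ellipsoid is projected onto the
#' window's principal directions, and directions whose RMS exceeds the
#' projected threshold are reconstructed from the retained directions using
#' the calibration covariance (conditional-expectation subspace projection).
#' Windows with no flagged direction pass through unchanged; corrected
#' windows are blended by weighted overlap-add.
#'
#' @param rec An `eeg_recording` (same channel set and order as calibration).
#' @param model An `asr_model`.
#' @return The corrected `eeg_recording`.
#' @export
asr_apply <- function(rec, model) {
  if (!is.null(model$labels) && !identical(rec$labels, model$labels)) {
    abort("channel set/order differs from the ASR calibration.")
  }
  x <- rec$eeg - model$center
  n <- ncol(x); nch <- nrow(x)
  w <- round(model$window_s * model$rate_hz)
  if (n < w) return(rec)
  hop <- max(1, floor(w / 2))
  starts <- unique(c(seq(1, n - w + 1, by = hop), n - w + 1))
  wgt <- sin(pi * (seq_len(w) - 0.5) / w)^2          # Hann taper for blending
  out <- matrix(0, nch, n)
  wsum <- numeric(n)
  V <- model$mixing
  Cc <- model$cov
  thr <- model$thresholds
  Tm <- V %*% diag(thr, nch)                         # threshold ellipsoid axes

  corrected <- FALSE
  for (s in starts) {
    idx <- s:(s + w - 1)
    xw <- x[, idx, drop = FALSE]
    Cw <- xw %*% t(xw) / w
    eg <- eigen(Cw, symmetric = TRUE)
    U <- eg$vectors
    comp_rms <- sqrt(pmax(eg$values, 0))
    thr_dir <- sqrt(colSums((t(Tm) %*% U)^2))
    flag <- is.finite(thr_dir) & comp_rms > thr_dir
    if (any(flag)) {
      corrected <- TRUE
      keep <- !flag
      yw <- t(U) %*% xw
      if (any(keep)) {
        Uk <- U[, keep, drop = FALSE]; Uf <- U[, flag, drop = FALSE]
        A <- (t(Uf) %*% Cc %*% Uk) %*%
          solve(t(Uk) %*% Cc %*% Uk + 1e-9 * diag(sum(keep)))
        yw[flag, ] <- A %*% yw[keep, , drop = FALSE]
      } else {
        yw[] <- 0
      }
      xw <- U %*% yw
    }
    out[, idx] <- out[, idx] + xw * rep(wgt, each = nch)
    wsum[idx] <- wsum[idx] + wgt
  }
  if (!corrected) return(rec)       # nothing flagged: exact pass-through
  ok <- wsum > 1e-12
  out[, ok] <- out[, ok] / rep(wsum[ok], each = nch)
  out[, !ok] <- x[, !ok]
  dimnames(out) <- dimnames(rec$eeg)
  rec$eeg <- out + model$center
  rec
}

#' Select clean calibration windows automatically
#'
#' Fallback when a block has no designated calibration segment: returns the
#' longest stretch of sliding windows whose total-power z-score lies within
#' `z_range`, concatenated (clean-window heuristic).
#'
#' @param eeg Channels x samples matrix.
#' @param rate_hz Sampling rate (Hz).
#' @param window_s Window length (s).
#' @param z_range Acceptable windowed-RMS z-score range.
#' @return Channels x samples matrix of concatenated clean windows.
#' @export
auto_calibration <- function(eeg, rate_hz, window_s = 1,
                             z_range = c(-3.5, 5.5)) {
  w <- round(window_s * rate_hz)
  starts <- seq(1, ncol(eeg) - w + 1, by = w)
  pow <- vapply(starts, function(s) {
    mean(eeg[, s:(s + w - 1), drop = FALSE]^2)
  }, numeric(1))
  lp <- log10(pow + 1e-30)
  z <- (lp - median(lp)) / (stats::IQR(lp) / 1.349 + 1e-12)
  ok <- starts[z >= z_range[1] & z <= z_range[2]]
  idx <- unlist(lapply(ok, function(s) s:(s + w - 1)))
  eeg[, idx, drop = FALSE]
}
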