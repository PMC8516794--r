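#' Detect flatline channels
#'
#' Flags channels containing a run of at least `max_flat_s` seconds during
#' which the absolute successive difference stays below `tol` (strict
#' threshold: a 59-s run at the 60-s default is not flagged).
#'
#' @param rec An `eeg_recording`.
#' @param max_flat_s Minimum flat duration to flag (s).
#' @param tol Per-sample successive-difference tolerance (uV).
#' @return Character vector of flagged channel labels.
#' @export
detect_flatlines <- function(rec, max_flat_s = 60, tol = 1e-6) {
  need <- max_flat_s * rec$rate
  flagged <- vapply(seq_len(nrow(rec$eeg)), function(ch) {
    flat <- abs(diff(rec$eeg[ch, ])) < tol
    if (!any(flat)) return(FALSE)
    r <- rle(flat)
    # a run of m flat differences spans m + 1 samples
    any(r$values & (r$lengths + 1) >= need)
  }, logical(1))
  rec$labels[flagged]
}

#' Amplitude and spectral channel rejection
#'
#' Two-stage bad-channel detection on filtered data, followed by the
#' block-discard rule. A channel is amplitude-bad when `|x|` exceeds
#' `amp_limit_uv` in more than `amp_frac` of samples. Spectral rejection then
#' z-scores the band-averaged log power (Welch estimate over `band_hz`)
#' across the remaining channels and flags `|z| > spec_z`. The block is
#' discarded when at least half of all channels are bad (including any
#' `prior_bad`, e.g. flatlines) or fewer than 4 channels survive.
#'
#' @param rec An `eeg_recording`.
#' @param amp_limit_uv Absolute amplitude criterion (uV).
#' @param amp_frac Fraction of samples allowed beyond the limit.
#' @param spec_z Spectral z-score threshold (SDs).
#' @param band_hz Frequency band for the spectral criterion (Hz); the default
#'   1--10 Hz matches data low-passed at 10 Hz.
#' @param prior_bad Labels already rejected upstream (flatlines).
#' @return A list of class `channel_report`: `flatline_bad`, `amplitude_bad`,
#'   `spectral_bad`, `interpolated` (filled later), `block_discarded`,
#'   `reason`.
#' @export
reject_channels <- function(rec, amp_limit_uv = 500, amp_frac = 0.001,
                            spec_z = 2, band_hz = c(1, 10),
                            prior_bad = character()) {
  labels <- rec$labels
  frac_over <- rowMeans(abs(rec$eeg) > amp_limit_uv)
  amplitude_bad <- setdiff(labels[frac_over > amp_frac], prior_bad)

  surv <- setdiff(labels, c(prior_bad, amplitude_bad))
  spectral_bad <- character()
  if (length(surv) >= 3) {
    idx <- match(surv, labels)
    logp <- vapply(idx, function(ch) {
      mean(log10(welch_psd(rec$eeg[ch, ], rec$rate, band_hz)$power + 1e-30))
    }, numeric(1))
    s <- sd(logp)
    z <- if (is.na(s) || s == 0) rep(0, length(logp)) else (logp - mean(logp)) / s
    spectral_bad <- surv[abs(z) > spec_z]
  }

  bad <- unique(c(prior_bad, amplitude_bad, spectral_bad))
  n_ch <- length(labels)
  discard <- length(bad) >= ceiling(n_ch / 2) || (n_ch - length(bad)) < 4
  structure(
    list(flatline_bad = prior_bad, amplitude_bad = amplitude_bad,
         spectral_bad = spectral_bad, interpolated = character(),
         block_discarded = discard,
         reason = if (discard) sprintf("%d of %d channels bad", length(bad), n_ch)
                  else NA_character_),
    class = "channel_report"
  )
}

#' @export
print.channel_report <- function(x, ...) {
  cat("<channel_report>\n")
  cat("  flatline: ", paste(x$flatline_bad, collapse = " "), "\n")
  cat("  amplitude:", paste(x$amplitude_bad, collapse = " "), "\n")
  cat("  spectral: ", paste(x$spectral_bad, collapse = " "), "\n")
  cat("  interpolated:", paste(x$interpolated, collapse = " "), "\n")
  cat("  block discarded:", x$block_discarded,
      if (!is.na(x$reason)) paste0(" (", x$reason, ")"), "\n")
  invisible(x)
}

#' All bad labels in a channel report
#' @param report A `channel_report`.
#' @return Character vector.
#' @export
bad_channels <- function(report) {
  unique(c(report$flatline_bad, report$amplitude_bad, report$spectral_bad))
}

#' Welch power spectral density
#'
#' Mean periodogram over 50%-overlapping Hann-windowed segments; returned on
#' the one-sided frequency grid, optionally restricted to a band.
#'
#' @param x Numeric signal.
#' @param rate_hz Sampling rate (Hz).
#' @param band_hz Optional `c(lo, hi)` band restriction.
#' @param seg_s Segment length (s).
#' @return Tibble with `freq_hz`, `power`.
#' @export
welch_psd <- function(x, rate_hz, band_hz = NULL, seg_s = 2) {
  nseg <- min(length(x), round(seg_s * rate_hz))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  starts <- seq(1, length(x) - nseg + 1, by = max(1, floor(nseg / 2)))
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * win
    acc <- acc + Mod(fft(seg))^2
  }
  p <- acc / length(starts) / sum(win^2) / rate_hz
  f <- (seq_len(nseg) - 1) * rate_hz / nseg
  keep <- f <= rate_hz / 2
  out <- tibble(freq_hz = f[keep], power = p[keep])
  if (!is.null(band_hz)) {
    out <- out[out$freq_hz >= band_hz[1] & out$freq_hz <= band_hz[2], ]
  }
  out
}
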