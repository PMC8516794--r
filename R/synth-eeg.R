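#' 1/f ("pink") noise
#'
#' Gaussian noise shaped in the frequency domain to a 1/f amplitude spectrum
#' (power ~ 1/f^2 per amplitude ~ 1/f would be Brownian; here amplitude
#' ~ 1/sqrt(f), i.e. power ~ 1/f), the canonical EEG background. The DC bin is
#' zeroed and the output rescaled to the requested RMS.
#'
#' @param n Number of samples.
#' @param rms Target root-mean-square amplitude.
#' @return Numeric vector of length `n`, mean ~ 0, sd ~ `rms`.
#' @export
pink_noise <- function(n, rms = 1) {
  if (rms == 0) return(numeric(n))
  nf <- nextn(n, c(2, 3, 5))     # smooth FFT length close to n
  w <- rnorm(nf)
  W <- fft(w)
  f <- c(1, seq_len(nf - 1))            # cycles per record; guard DC
  f <- pmin(f, nf - f + 1)              # fold to two-sided frequency
  W <- W / sqrt(f)
  W[1] <- 0
  x <- Re(fft(W, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  x * rms / sd(x)
}

#' Stimulus-locked ERP template on the bipolar channel
#'
#' The deterministic response added (per channel loading) at each stimulus
#' onset: an early negative Gaussian component peaking at 150 ms (SD 25 ms)
#' and a later positive Gaussian P3 component peaking at `peak_ms` (SD 70 ms).
#' The P3 gain is solved so that the template's mean over `peak_ms +/- 100 ms`
#' equals `window_mean_uv` exactly, including whatever the early component
#' contributes inside that window.
#'
#' @param rate Sampling rate (Hz).
#' @param peak_ms P3 peak latency (ms).
#' @param window_mean_uv Required mean amplitude in the peak +/- 100 ms window
#'   (uV, bipolar scale).
#' @param span_s Template support relative to stimulus onset (s).
#' @param n1_uv Amplitude of the early negative component (uV, negative).
#' @return List with `template` (numeric vector over `[0, span_s)`) and `t`
#'   (times in s).
#' @export
erp_template <- function(rate, peak_ms, window_mean_uv,
                         span_s = 0.8, n1_uv = -1) {
  t_ms <- seq(0, span_s * 1000 - 1000 / rate, by = 1000 / rate)
  n1 <- n1_uv * exp(-(t_ms - 150)^2 / (2 * 25^2))
  p3 <- exp(-(t_ms - peak_ms)^2 / (2 * 70^2))
  win <- t_ms >= peak_ms - 100 & t_ms <= peak_ms + 100
  gain <- (window_mean_uv - mean(n1[win])) / mean(p3[win])
  list(template = n1 + gain * p3, t = t_ms / 1000)
}

#' Per-channel ERP loadings for the cEEGrid montage
#'
#' The bipolar contrast mean(R2, R3) - mean(R6, R7) is the analysis channel;
#' loadings are fixed so that this contrast reproduces the bipolar template at
#' unit gain: +0.5 on R2/R3 (and their left homologues), -0.5 on R6/R7, and a
#' linear gradient along each grid for the remaining positions.
#'
#' @param labels Channel labels.
#' @return Named numeric vector of loadings.
#' @export
channel_loadings <- function(labels = ceegrid_labels()) {
  pos_load <- c("1" = 0.4, "2" = 0.5, "3" = 0.5, "4a" = 0.25, "4b" = 0.1,
                "5" = -0.2, "6" = -0.5, "7" = -0.5, "8" = -0.4, "9" = -0.3)
  pos <- sub("^[LR]", "", labels)
  out <- unname(pos_load[pos])
  if (anyNA(out)) abort("unknown cEEGrid position label.")
  names(out) <- labels
  out
}

#' Simulate continuous EEG for one oddball block
#'
#' Produces an artifact-free `eeg_recording`: a 1-minute calibration segment,
#' then the block's trials. Each stimulus adds the stereotyped ERP template
#' (early negativity + P3 peaking at the variant's latency), scaled per
#' channel by the montage loadings so the vertical bipolar window mean equals
#' the profile's standard amplitude (or standard + target increase). The
#' background is 1/f noise at `profile$noise_uv_rms` plus 25%-RMS white sensor
#' noise per channel.
#'
#' @param profile A [participant_profile()].
#' @param schedule An `oddball_schedule`.
#' @param config A [session_config()].
#' @param participant,block Identifiers stored in `meta`.
#' @param seed Optional integer seed.
#' @return An `eeg_recording` with events `calibration_start`, `block_start`
#'   and one marker per trial (role and scored flag carried along).
#' @export
simulate_eeg <- function(profile, schedule, config,
                         participant = 1L, block = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate <- config$eeg_rate_hz
  variant <- attr(schedule, "variant")
  peak_ms <- if (variant == "rapid") profile$erp_peak_rapid_ms else
    profile$erp_peak_sporadic_ms
  amp_std <- profile$erp_standard_uv[[variant]]
  amp_tgt <- amp_std + profile$erp_target_delta_uv[[variant]]

  block_span <- max(schedule$onset_s + schedule$duration_s) + 1
  n <- ceiling((config$calibration_s + block_span) * rate)
  labels <- config$channel_labels
  load <- channel_loadings(labels)

  eeg <- matrix(0, length(labels), n)
  for (ch in seq_along(labels)) {
    eeg[ch, ] <- pink_noise(n, profile$noise_uv_rms) +
      rnorm(n, 0, 0.25 * profile$noise_uv_rms)
  }

  tpl_std <- erp_template(rate, peak_ms, amp_std)$template
  tpl_tgt <- erp_template(rate, peak_ms, amp_tgt)$template
  len <- length(tpl_std)
  for (i in seq_len(nrow(schedule))) {
    i0 <- round((config$calibration_s + schedule$onset_s[i]) * rate) + 1
    idx <- i0:(i0 + len - 1)
    keep <- idx <= n
    tpl <- if (schedule$role[i] == "target") tpl_tgt else tpl_std
    eeg[, idx[keep]] <- eeg[, idx[keep]] +
      outer(load, tpl[keep])
  }

  events <- bind_rows(
    tibble(time_s = 0, label = "calibration_start", role = NA_character_,
           scored = NA, trial = NA_integer_),
    tibble(time_s = config$calibration_s, label = "block_start",
           role = NA_character_, scored = NA, trial = NA_integer_),
    tibble(time_s = config$calibration_s + schedule$onset_s,
           label = schedule$marker, role = schedule$role,
           scored = schedule$scored, trial = schedule$trial)
  )

  new_recording(
    eeg, rate, labels, events,
    meta = list(participant = participant, block = block, variant = variant,
                calibration_s = config$calibration_s)
  )
}
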