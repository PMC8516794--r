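#' Artifact plan for the synthetic generator
#'
#' Describes the artifact mix injected into a clean recording: high-variance
#' bursts (time-locked to high-displacement periods when a gyroscope stream is
#' present), long flatline segments on designated channels, broadband noise on
#' designated channels, and sparse large transients.
#'
#' @param burst_rate_per_min Expected burst count per minute (outside the
#'   calibration segment).
#' @param burst_gain Burst amplitude as a multiple of the channel's background
#'   RMS.
#' @param burst_dur_s Burst duration (s).
#' @param flatline Tibble with `channel`, `start_s`, `dur_s` rows.
#' @param noisy Tibble with `channel`, `gain` rows (white noise at `gain` x
#'   background RMS added over the whole block).
#' @param transient_rate_per_min Expected rate of single-sample +/-500 uV-scale
#'   transients.
#' @param transient_uv Transient amplitude (uV).
#' @return A list of class `artifact_plan`. `empty_artifact_plan()` injects
#'   nothing.
#' @export
artifact_plan <- function(burst_rate_per_min = 2, burst_gain = 20,
                          burst_dur_s = 0.5,
                          flatline = tibble(channel = character(),
                                            start_s = numeric(),
                                            dur_s = numeric()),
                          noisy = tibble(channel = character(),
                                         gain = numeric()),
                          transient_rate_per_min = 0.5,
                          transient_uv = 500) {
  structure(
    list(burst_rate_per_min = burst_rate_per_min, burst_gain = burst_gain,
         burst_dur_s = burst_dur_s, flatline = flatline, noisy = noisy,
         transient_rate_per_min = transient_rate_per_min,
         transient_uv = transient_uv),
    class = "artifact_plan"
  )
}

#' @rdname artifact_plan
#' @export
empty_artifact_plan <- function() {
  artifact_plan(burst_rate_per_min = 0, transient_rate_per_min = 0)
}

#' Inject artifacts into a clean recording
#'
#' Adds the plan's artifacts outside the calibration segment and returns both
#' the contaminated recording and a ground-truth log sufficient to locate
#' every insertion (used as the oracle for the cleaning stages).
#'
#' @param rec An `eeg_recording`.
#' @param plan An [artifact_plan()].
#' @param seed Optional integer seed.
#' @return List with `recording` and `log` (tibble: `kind`, `channel`,
#'   `start_s`, `end_s`, `param`).
#' @export
inject_artifacts <- function(rec, plan, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eeg <- rec$eeg
  rate <- rec$rate
  n <- ncol(eeg)
  dur <- n / rate
  cal_s <- rec$meta$calibration_s %||% 0
  log <- tibble(kind = character(), channel = character(),
                start_s = numeric(), end_s = numeric(), param = numeric())
  bg_rms <- apply(eeg, 1, sd)

  # (a) high-variance bursts, time-locked to high displacement when available
  n_burst <- stats::rpois(1, plan$burst_rate_per_min * (dur - cal_s) / 60)
  if (n_burst > 0) {
    if (!is.null(rec$gyro)) {
      d <- displacement(rec$gyro)$d
      g_rate <- rec$gyro_rate
      ok <- which(d > quantile(d, 0.9))
      ok <- ok[ok / g_rate > cal_s & ok / g_rate < dur - plan$burst_dur_s]
      starts_s <- if (length(ok)) (sample(ok, n_burst, replace = TRUE) / g_rate) else
        runif(n_burst, cal_s, dur - plan$burst_dur_s)
    } else {
      starts_s <- runif(n_burst, cal_s, dur - plan$burst_dur_s)
    }
    for (s0 in starts_s) {
      idx <- round(s0 * rate):(round((s0 + plan$burst_dur_s) * rate))
      idx <- idx[idx >= 1 & idx <= n]
      # spatially coherent burst: one random topography across channels
      topo <- rnorm(nrow(eeg))
      topo <- topo / sqrt(mean(topo^2))
      shape <- sin(pi * seq_along(idx) / length(idx))^2
      eeg[, idx] <- eeg[, idx] +
        outer(topo * plan$burst_gain * mean(bg_rms), shape * rnorm(length(idx)))
      log <- bind_rows(log, tibble(kind = "burst", channel = NA_character_,
                                   start_s = s0, end_s = s0 + plan$burst_dur_s,
                                   param = plan$burst_gain))
    }
  }

  # (b) flatline segments
  for (i in seq_len(nrow(plan$flatline))) {
    fl <- plan$flatline[i, ]
    if (fl$start_s + fl$dur_s > dur) abort("flatline window exceeds recording span.")
    ch <- match(fl$channel, rec$labels)
    idx <- (round(fl$start_s * rate) + 1):min(n, round((fl$start_s + fl$dur_s) * rate))
    eeg[ch, idx] <- eeg[ch, idx[1]]
    log <- bind_rows(log, tibble(kind = "flatline", channel = fl$channel,
                                 start_s = fl$start_s,
                                 end_s = fl$start_s + fl$dur_s, param = NA_real_))
  }

  # (c) broadband-noise channels: a channel fault spans the whole recording,
  # calibration segment included
  for (i in seq_len(nrow(plan$noisy))) {
    nz <- plan$noisy[i, ]
    ch <- match(nz$channel, rec$labels)
    eeg[ch, ] <- eeg[ch, ] + rnorm(n, 0, nz$gain * bg_rms[ch])
    log <- bind_rows(log, tibble(kind = "noisy", channel = nz$channel,
                                 start_s = 0, end_s = dur, param = nz$gain))
  }

  # (d) sparse large transients
  n_tr <- stats::rpois(1, plan$transient_rate_per_min * (dur - cal_s) / 60)
  if (n_tr > 0) {
    at <- runif(n_tr, cal_s, dur)
    chs <- sample(seq_len(nrow(eeg)), n_tr, replace = TRUE)
    for (k in seq_len(n_tr)) {
      i0 <- max(1, min(n, round(at[k] * rate)))
      eeg[chs[k], i0] <- eeg[chs[k], i0] + sample(c(-1, 1), 1) * plan$transient_uv
      log <- bind_rows(log, tibble(kind = "transient", channel = rec$labels[chs[k]],
                                   start_s = at[k], end_s = at[k],
                                   param = plan$transient_uv))
    }
  }

  out <- rec
  out$eeg <- eeg
  list(recording = out, log = log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
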