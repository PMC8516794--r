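#' Clean one continuous block recording
#'
#' Runs the fixed cleaning chain on an `eeg_recording`:
#' zero-phase low-pass (10 Hz) and high-pass (0.1 Hz) filtering, flatline
#' channel detection (60 s), ASR burst correction (burst criterion 20)
#' calibrated on the block's designated calibration segment (or automatic
#' clean-window selection when none is marked), amplitude (+/- 500 uV) and
#' spectral (2 SD) channel rejection, then either block discard (when at
#' least half the channels are bad or fewer than 4 survive) or
#' spherical-spline interpolation of the bad channels.
#'
#' @param rec An `eeg_recording`.
#' @param config A [pipeline_config()] list (stage parameters).
#' @param coords Electrode coordinates for interpolation.
#' @return A list of class `cleaned_block`: `recording` (cleaned; `NULL` when
#'   discarded), `report` (a `channel_report` with `interpolated` filled in),
#'   `asr_model`.
#' @export
#' @examples
#' cfg <- session_config(block_plan = "rapid", n_trials = 10)
#' ses <- simulate_session(participant_profile(), cfg, seed = 2)
#' out <- clean_recording(ses$recordings[[1]])
#' out$report
clean_recording <- function(rec, config = pipeline_config(),
                            coords = ceegrid_coords(rec$labels)) {
  p <- config

  rec <- filter_recording(rec, p$lowpass_hz, p$lowpass_order,
                          p$highpass_hz, p$highpass_order)

  flat <- detect_flatlines(rec, p$flatline_s)

  # ASR on the channels that are not flat
  keep <- setdiff(rec$labels, flat)
  sub <- rec
  sub$eeg <- rec$eeg[match(keep, rec$labels), , drop = FALSE]
  sub$labels <- keep

  cal <- calibration_segment(sub, p$asr_window_s)
  model <- NULL
  if (!is.null(cal)) {
    model <- tryCatch(
      asr_calibrate(cal, rec$rate, p$asr_cutoff_k, p$asr_window_s,
                    labels = keep),
      error = function(e) { warn(conditionMessage(e)); NULL }
    )
  }
  if (!is.null(model)) sub <- asr_apply(sub, model)
  rec$eeg[match(keep, rec$labels), ] <- sub$eeg

  report <- reject_channels(sub, p$amp_limit_uv, p$amp_frac, p$spec_z,
                            p$spec_band_hz, prior_bad = flat)

  if (report$block_discarded) {
    return(structure(list(recording = NULL, report = report,
                          asr_model = model), class = "cleaned_block"))
  }
  bad <- bad_channels(report)
  if (length(bad)) {
    rec <- interpolate_spherical(rec, bad, coords)
    report$interpolated <- bad
  }
  structure(list(recording = rec, report = report, asr_model = model),
            class = "cleaned_block")
}

# designated calibration segment (calibration_start .. block_start markers),
# or automatic clean-window selection as fallback
calibration_segment <- function(rec, window_s) {
  ev <- rec$events
  i0 <- ev$time_s[ev$label == "calibration_start"]
  i1 <- ev$time_s[ev$label == "block_start"]
  if (length(i0) == 1 && length(i1) == 1 && i1 - i0 >= 30) {
    idx <- (round(i0 * rec$rate) + 1):(round(i1 * rec$rate))
    rec$eeg[, idx, drop = FALSE]
  } else {
    cal <- auto_calibration(rec$eeg, rec$rate)
    if (ncol(cal) >= 30 * rec$rate) cal else NULL
  }
}

#' Pipeline stage parameters
#'
#' All tunable cleaning/analysis parameters with the standard defaults:
#' 10 Hz low-pass (order 330), 0.1 Hz high-pass (order 8250), 60-s flatline
#' criterion, ASR burst criterion 20 with 0.5-s windows, +/-500 uV amplitude
#' criterion (bad when exceeded in > 0.1% of samples), spectral rejection at
#' 2 SDs over 1--10 Hz, epoch span -0.2--0.8 s with -200--0 ms baseline,
#' joint-probability threshold 2 SDs, P3 search range 200--600 ms with a
#' +/-100 ms extraction window, movement threshold median + 4 IQR, 10-s
#' moving-median smoothing, alpha 0.05 with Bonferroni correction.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    lowpass_hz = 10, lowpass_order = 330,
    highpass_hz = 0.1, highpass_order = 8250,
    flatline_s = 60,
    asr_cutoff_k = 20, asr_window_s = 0.5,
    amp_limit_uv = 500, amp_frac = 0.001,
    spec_z = 2, spec_band_hz = c(1, 10),
    epoch_span_s = c(-0.2, 0.8), baseline_s = c(-0.2, 0),
    jointprob_z = 2,
    p3_search_ms = c(200, 600), p3_halfwidth_ms = 100,
    movement_iqr_mult = 4, smooth_s = 10,
    alpha = 0.05, p_adjust = "bonferroni"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) abort(paste("unknown parameters:", paste(bad, collapse = ", ")))
  defaults[names(over)] <- over
  defaults
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()] list.
#' @return `read_pipeline_config()` returns the config list with defaults for
#'   any unspecified parameter.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
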