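#' Construct a multichannel recording
#'
#' Container for one synchronized block recording: EEG (channels x samples,
#' microvolts), optional 3-axis gyroscope angular rates (deg/s), and an event
#' marker stream, all on one clock starting at t = 0.
#'
#' @param eeg Numeric matrix, channels x samples (uV).
#' @param rate Sampling rate of `eeg` (Hz).
#' @param labels Channel labels (length = `nrow(eeg)`).
#' @param events Tibble with at least `time_s` and `label`.
#' @param gyro Optional 3 x samples matrix (yaw, pitch, roll rates).
#' @param gyro_rate Gyroscope sampling rate (Hz).
#' @param meta Named list of identifiers (participant, block, variant, ...).
#'
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(eeg, rate, labels, events = tibble(time_s = numeric(),
                                                             label = character()),
                          gyro = NULL, gyro_rate = rate, meta = list()) {
  stopifnot(is.matrix(eeg), nrow(eeg) == length(labels))
  if (!is.null(gyro)) stopifnot(is.matrix(gyro), nrow(gyro) == 3)
  dur <- ncol(eeg) / rate
  if (nrow(events) && any(events$time_s < 0 | events$time_s > dur)) {
    abort("event times fall outside the recording span.")
  }
  structure(
    list(eeg = eeg, rate = rate, labels = labels, events = events,
         gyro = gyro, gyro_rate = gyro_rate, meta = meta),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$eeg), ncol(x$eeg), x$rate, ncol(x$eeg) / x$rate
  ))
  cat(sprintf("  channels: %s\n", paste(x$labels, collapse = " ")))
  cat(sprintf("  events: %d; gyro: %s\n", nrow(x$events),
              if (is.null(x$gyro)) "none" else
                sprintf("3 x %d @ %g Hz", ncol(x$gyro), x$gyro_rate)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `eeg_recording`.
#' @return Duration (s).
#' @export
recording_duration <- function(rec) ncol(rec$eeg) / rec$rate
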