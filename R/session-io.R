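#' Write / read a recording in the native session layout
#'
#' The canonical on-disk layout for one block recording: EEG as float64
#' little-endian binary (`eeg.bin`, channel-major frames) with a JSON header
#' (`header.json`: rates, labels, shapes, meta), events as TSV
#' (`events.tsv`), gyroscope as TSV (`gyro.tsv`). The binary round trip is
#' bit-exact.
#'
#' @param rec An `eeg_recording`.
#' @param dir Directory to create/fill.
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns the reconstructed `eeg_recording`.
#' @export
#' @examples
#' rec <- new_recording(matrix(rnorm(100), 2), 50, c("R2", "R3"))
#' d <- file.path(tempdir(), "ses"); write_session(rec, d)
#' identical(read_session(d)$eeg, rec$eeg)
write_session <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- list(
    rate = rec$rate, labels = rec$labels,
    n_channels = nrow(rec$eeg), n_samples = ncol(rec$eeg),
    gyro_rate = rec$gyro_rate, has_gyro = !is.null(rec$gyro),
    meta = rec$meta
  )
  jsonlite::write_json(hdr, file.path(dir, "header.json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(file.path(dir, "eeg.bin"), "wb")
  writeBin(as.numeric(rec$eeg), con, size = 8, endian = "little")
  close(con)
  write.table(as.data.frame(rec$events), file.path(dir, "events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(rec$gyro)) {
    write.table(as.data.frame(t(rec$gyro)), file.path(dir, "gyro.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  hfile <- file.path(dir, "header.json")
  if (!file.exists(hfile)) abort(sprintf("missing stream: %s", hfile))
  hdr <- jsonlite::read_json(hfile, simplifyVector = TRUE)
  bfile <- file.path(dir, "eeg.bin")
  if (!file.exists(bfile)) abort("missing stream: eeg.bin")
  con <- file(bfile, "rb")
  x <- readBin(con, "numeric", n = hdr$n_channels * hdr$n_samples, size = 8,
               endian = "little")
  close(con)
  eeg <- matrix(x, nrow = hdr$n_channels)
  efile <- file.path(dir, "events.tsv")
  events <- if (file.exists(efile)) {
    as_tibble(read.table(efile, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE))
  } else tibble(time_s = numeric(), label = character())
  gfile <- file.path(dir, "gyro.tsv")
  gyro <- NULL
  if (isTRUE(hdr$has_gyro)) {
    if (!file.exists(gfile)) {
      warn("header announces a gyroscope stream but gyro.tsv is missing; movement stage will be unavailable.")
    } else {
      gyro <- t(as.matrix(read.table(gfile, header = TRUE, sep = "\t")))
      rownames(gyro) <- c("yaw", "pitch", "roll")
    }
  }
  meta <- as.list(hdr$meta)
  new_recording(eeg, hdr$rate, hdr$labels, events, gyro,
                hdr$gyro_rate %||% hdr$rate, meta)
}
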