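#' Double-tone stimulus specification
#'
#' Each oddball stimulus is a pair of tones sharing one fundamental frequency:
#' a 700-ms tone, a 100-ms silent gap, and a 500-ms tone, each with 5-ms linear
#' rise/fall ramps (1300 ms total at the defaults). One fundamental is assigned
#' to the standard and the other to the target.
#'
#' @param f0_standard_hz,f0_target_hz Fundamental frequencies (Hz) of the
#'   standard and target double tones.
#' @param tone1_ms,gap_ms,tone2_ms Durations (ms) of first tone, silent gap and
#'   second tone.
#' @param ramp_ms Linear on/off ramp duration (ms); must be shorter than each
#'   tone.
#' @param audio_rate_hz Audio sampling rate (Hz).
#'
#' @return A list of class `double_tone_spec`.
#' @export
#' @examples
#' spec <- double_tone_spec()
#' spec$total_ms
double_tone_spec <- function(f0_standard_hz = 100, f0_target_hz = 300,
                             tone1_ms = 700, gap_ms = 100, tone2_ms = 500,
                             ramp_ms = 5, audio_rate_hz = 44100) {
  stopifnot(tone1_ms > 0, tone2_ms > 0, gap_ms >= 0, audio_rate_hz > 0)
  if (ramp_ms >= min(tone1_ms, tone2_ms)) {
    abort("`ramp_ms` must be shorter than each tone duration.")
  }
  structure(
    list(
      f0_standard_hz = f0_standard_hz, f0_target_hz = f0_target_hz,
      tone1_ms = tone1_ms, gap_ms = gap_ms, tone2_ms = tone2_ms,
      ramp_ms = ramp_ms, audio_rate_hz = audio_rate_hz,
      total_ms = tone1_ms + gap_ms + tone2_ms
    ),
    class = "double_tone_spec"
  )
}

#' Generate a standard/target role sequence
#'
#' Draws a randomized trial-role sequence under the oddball run constraints:
#' the first four trials are always standards, the target count is exact
#' (`round(n_trials * target_fraction)`), and no more than two targets occur in
#' succession.
#'
#' @param n_trials Total number of scored trials (>= 4).
#' @param target_fraction Fraction of target trials (default 0.3, i.e. 48 of
#'   160).
#' @param seed Optional integer seed; when supplied the draw is deterministic.
#'
#' @return Character vector of length `n_trials` with values `"standard"` /
#'   `"target"`.
#' @export
#' @examples
#' roles <- generate_sequence(160, 0.3, seed = 1)
#' table(roles)
generate_sequence <- function(n_trials, target_fraction = 0.3, seed = NULL) {
  stopifnot(n_trials >= 4)
  if (!is.null(seed)) set.seed(seed)
  n_targets <- round(n_trials * target_fraction)
  n_free <- n_trials - 4L
  # with a max run of 2 targets among the n_free randomized positions, at most
  # ceiling(2/3 * n_free) targets can be placed
  if (n_targets > ceiling(2 / 3 * n_free)) {
    abort(sprintf(
      "cannot place %d targets in %d randomized positions without a run of 3",
      n_targets, n_free
    ))
  }
  roles <- rep("standard", n_trials)
  if (n_targets == 0) return(roles)
  # rejection-free sequential construction: shuffle, then repair runs of >= 3
  # by resampling is wasteful at high target fractions; instead place targets
  # one block at a time into a random arrangement and repair locally.
  repeat {
    free <- sample(c(rep("target", n_targets), rep("standard", n_free - n_targets)))
    runs <- rle(free)
    bad <- which(runs$values == "target" & runs$lengths > 2)
    if (length(bad) == 0) {
      roles[5:n_trials] <- free
      return(roles)
    }
    # local repair: move one target from each overlong run into a random slot
    # that does not create a new run of three
    seq_ok <- TRUE
    for (b in bad) {
      ends <- cumsum(runs$lengths)
      excess <- runs$lengths[b] - 2L
      run_end <- ends[b]
      for (k in seq_len(excess)) {
        pos <- run_end - (k - 1L)
        cand <- which(free == "standard")
        cand <- cand[vapply(cand, function(i) {
          tmp <- free
          tmp[pos] <- "standard"; tmp[i] <- "target"
          r <- rle(tmp)
          !any(r$values == "target" & r$lengths > 2)
        }, logical(1))]
        if (length(cand) == 0) { seq_ok <- FALSE; break }
        i <- if (length(cand) == 1) cand else sample(cand, 1)
        free[pos] <- "standard"; free[i] <- "target"
      }
      if (!seq_ok) break
      runs <- rle(free)
    }
    if (seq_ok && !any(runs$values == "target" & runs$lengths > 2)) {
      roles[5:n_trials] <- free
      return(roles)
    }
  }
}

#' Generate a rapid or sporadic oddball block schedule
#'
#' Builds the ordered trial table for one oddball block. In the rapid variant
#' the inter-trial interval (offset of the previous double tone to onset of the
#' next) is uniform on 0.5--0.9 s; in the sporadic variant it is uniform on
#' 56.2--61.2 s. Sporadic blocks additionally carry ten unscored familiarization
#' trials with rapid intervals (alternating target/standard) at each end, and a
#' rest-break marker after 80 scored trials.
#'
#' @param variant `"rapid"` or `"sporadic"`.
#' @param n_trials Number of scored trials (default 160).
#' @param target_fraction Fraction of targets among scored trials (default 0.3).
#' @param spec A [double_tone_spec()].
#' @param seed Optional integer seed.
#'
#' @return A tibble of class `oddball_schedule` with columns `trial`, `role`,
#'   `onset_s`, `duration_s`, `scored`, `marker`, and attributes `variant`,
#'   `isi_range_s`, `seed`.
#' @export
#' @examples
#' sch <- generate_schedule("rapid", seed = 1)
#' dplyr::count(sch, role)
generate_schedule <- function(variant = c("rapid", "sporadic"),
                              n_trials = 160, target_fraction = 0.3,
                              spec = double_tone_spec(), seed = NULL) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  isi_range <- switch(variant,
    rapid = c(0.5, 0.9),
    sporadic = c(56.2, 61.2)
  )
  rapid_isi <- c(0.5, 0.9)
  dur <- spec$total_ms / 1000

  roles <- generate_sequence(n_trials, target_fraction)
  scored <- tibble(
    role = roles,
    isi_s = runif(n_trials, isi_range[1], isi_range[2]),
    scored = TRUE,
    marker = "trial"
  )

  if (variant == "sporadic") {
    fam <- function() tibble(
      role = rep(c("target", "standard"), 5),
      isi_s = runif(10, rapid_isi[1], rapid_isi[2]),
      scored = FALSE,
      marker = "familiarization"
    )
    trials <- bind_rows(fam(), scored, fam())
    rest_after <- which(trials$scored)[80]
    trials$marker[rest_after] <- "trial_rest_break_after"
  } else {
    trials <- scored
  }

  # first ISI precedes the first trial (block start to first onset)
  trials <- trials %>%
    mutate(
      duration_s = dur,
      onset_s = cumsum(.data$isi_s + dur) - dur,
      trial = row_number()
    ) %>%
    select("trial", "role", "onset_s", "duration_s", "scored", "marker")

  structure(
    trials,
    variant = variant, isi_range_s = isi_range, seed = seed,
    stimulus = spec,
    class = c("oddball_schedule", class(trials))
  )
}

#' Summary statistics of a schedule
#'
#' @param schedule An `oddball_schedule`.
#' @return One-row tibble with trial counts, block duration and target rate.
#' @export
schedule_summary <- function(schedule) {
  sc <- schedule[schedule$scored, ]
  dur_s <- max(schedule$onset_s + schedule$duration_s)
  tibble(
    variant = attr(schedule, "variant"),
    n_trials = nrow(sc),
    n_standards = sum(sc$role == "standard"),
    n_targets = sum(sc$role == "target"),
    duration_s = dur_s,
    targets_per_min = sum(sc$role == "target") / (dur_s / 60),
    min_per_target = (dur_s / 60) / sum(sc$role == "target")
  )
}

#' Render a double-tone audio waveform
#'
#' Synthesizes the two-tone stimulus at the audio rate: harmonic-series tones
#' (all harmonics, 1/k amplitude decay, for the oboe-like standard; odd
#' harmonics only for the clarinet-like target) with linear on/off ramps,
#' separated by the silent gap. Both roles are RMS-normalized to a common
#' intensity.
#'
#' @param spec A [double_tone_spec()].
#' @param role `"standard"` or `"target"`.
#' @param rms Target root-mean-square amplitude over the sounding portions.
#' @return Numeric waveform of `spec$total_ms` duration at `spec$audio_rate_hz`.
#' @export
#' @examples
#' w <- render_double_tone(double_tone_spec(), "standard")
#' length(w)
render_double_tone <- function(spec, role = c("standard", "target"), rms = 0.1) {
  role <- match.arg(role)
  f0 <- if (role == "standard") spec$f0_standard_hz else spec$f0_target_hz
  harmonics <- if (role == "standard") 1:8 else seq(1, 15, by = 2)
  fs <- spec$audio_rate_hz

  tone <- function(dur_ms) {
    n <- round(dur_ms / 1000 * fs)
    t <- (seq_len(n) - 1) / fs
    keep <- harmonics[harmonics * f0 < fs / 2]
    x <- rowSums(vapply(keep, function(k) sin(2 * pi * k * f0 * t) / k,
                        numeric(n)))
    nr <- round(spec$ramp_ms / 1000 * fs)
    ramp <- seq(0, 1, length.out = nr)
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[n - nr + seq_len(nr)] <- x[n - nr + seq_len(nr)] * rev(ramp)
    x
  }

  x1 <- tone(spec$tone1_ms)
  gap <- numeric(round(spec$gap_ms / 1000 * fs))
  x2 <- tone(spec$tone2_ms)
  w <- c(x1, gap, x2)
  sounding <- c(x1, x2)
  w * rms / sqrt(mean(sounding^2))
}

#' Write / read a schedule as a TSV event table
#'
#' The event table carries `onset_s`, `role`, `scored`, `marker`; a JSON
#' sidecar stores the variant, ISI range, stimulus spec and seed.
#'
#' @param schedule An `oddball_schedule`.
#' @param path TSV file path (sidecar written as `<path>.json`).
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns the reconstructed `oddball_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  write.table(as.data.frame(schedule), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(
    variant = attr(schedule, "variant"),
    isi_range_s = attr(schedule, "isi_range_s"),
    seed = attr(schedule, "seed"),
    stimulus = unclass(attr(schedule, "stimulus"))
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    df,
    variant = side$variant, isi_range_s = side$isi_range_s, seed = side$seed,
    stimulus = do.call(double_tone_spec,
                       side$stimulus[setdiff(names(side$stimulus), "total_ms")]),
    class = c("oddball_schedule", class(df))
  )
}
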