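#' Extract stimulus-locked epochs
#'
#' Cuts epochs on `span_s` (half-open, default [-0.2, 0.8) s, i.e. 250
#' samples at 250 Hz) around every scored trial onset and baseline-corrects
#' each epoch/channel by its mean over `baseline_s`. Familiarization trials
#' are never extracted. The first two scored epochs of the block are flagged
#' `first_two`, targets whose behaviour row is a miss are flagged
#' `missed_target`, and trials whose window leaves the recording are flagged
#' `out_of_range`; only unflagged epochs are `kept`.
#'
#' @param rec An `eeg_recording` (events must carry `trial`, `role`,
#'   `scored`).
#' @param behavior Optional behaviour tibble (from [simulate_behavior()]);
#'   used for the missed-target exclusion.
#' @param span_s Epoch span relative to onset, half-open.
#' @param baseline_s Baseline window.
#' @return A list of class `epoch_set`: `data` (epochs x channels x samples
#'   array), `t` (sample times, s), `roles`, `trial`, `kept`, `reason`,
#'   `labels`, `rate`, `meta`.
#' @export
extract_epochs <- function(rec, behavior = NULL, span_s = c(-0.2, 0.8),
                           baseline_s = c(-0.2, 0)) {
  ev <- rec$events %>%
    filter(!is.na(.data$scored), .data$scored) %>%
    arrange(.data$time_s)
  n_pre <- round(-span_s[1] * rec$rate)
  n_len <- round((span_s[2] - span_s[1]) * rec$rate)
  t <- (seq_len(n_len) - 1 - n_pre) / rec$rate
  bl <- t >= baseline_s[1] & t < baseline_s[2]

  n_ep <- nrow(ev)
  data <- array(NA_real_, c(n_ep, nrow(rec$eeg), n_len))
  reason <- rep("none", n_ep)
  for (e in seq_len(n_ep)) {
    i0 <- round(ev$time_s[e] * rec$rate) + 1 - n_pre
    idx <- i0:(i0 + n_len - 1)
    if (idx[1] < 1 || idx[n_len] > ncol(rec$eeg)) {
      reason[e] <- "out_of_range"
      next
    }
    ep <- rec$eeg[, idx, drop = FALSE]
    data[e, , ] <- ep - rowMeans(ep[, bl, drop = FALSE])
  }
  reason[which(reason == "none")[1:min(2, n_ep)]] <- "first_two"
  if (!is.null(behavior) && nrow(behavior)) {
    missed <- behavior$trial[behavior$miss]
    reason[ev$trial %in% missed & reason == "none"] <- "missed_target"
  }
  structure(
    list(data = data, t = t, roles = ev$role, trial = ev$trial,
         kept = reason == "none", reason = reason, labels = rec$labels,
         rate = rec$rate, meta = rec$meta),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d kept) x %d channels x %d samples @ %g Hz\n",
              length(x$kept), sum(x$kept), dim(x$data)[2], dim(x$data)[3],
              x$rate))
  print(table(reason = x$reason))
  invisible(x)
}

#' Joint-probability epoch rejection
#'
#' Single-pass rejection of improbable epochs: for every channel the pooled
#' value distribution over kept epochs is estimated with a fixed-bin
#' histogram; each epoch's joint log-probability is the sum of log bin
#' probabilities of its samples. Epochs are rejected when the z-score of this
#' quantity across epochs exceeds the threshold on any single channel
#' (local) or on the channel mean (global). A degenerate distribution (all
#' values equal) yields no rejections.
#'
#' @param eset An `epoch_set` with at least 10 kept epochs.
#' @param z_thresh Rejection threshold in SDs (local and global).
#' @param n_bins Histogram bins over the pooled per-channel range.
#' @return The `epoch_set` with rejected epochs marked `jointprob_local` /
#'   `jointprob_global`.
#' @export
reject_jointprob <- function(eset, z_thresh = 2, n_bins = 100) {
  keep_idx <- which(eset$kept)
  if (length(keep_idx) < 10) abort("need at least 10 kept epochs.")
  n_ch <- dim(eset$data)[2]
  jp <- matrix(0, length(keep_idx), n_ch)
  for (ch in seq_len(n_ch)) {
    vals <- eset$data[keep_idx, ch, ]
    rng <- range(vals)
    if (diff(rng) == 0) next
    brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- pmin(n_bins, pmax(1L, findInterval(vals, brk, rightmost.closed = TRUE)))
    p <- tabulate(bin, n_bins) / length(vals)
    logp <- log(pmax(p, 1e-12))
    jp[, ch] <- rowSums(matrix(logp[bin], nrow = length(keep_idx)))
  }
  zcol <- function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  local_z <- apply(jp, 2, zcol)
  if (is.null(dim(local_z))) local_z <- matrix(local_z, ncol = n_ch)
  global_z <- zcol(rowMeans(jp))
  bad_local <- apply(abs(local_z) > z_thresh, 1, any)
  bad_global <- abs(global_z) > z_thresh
  eset$reason[keep_idx[bad_local]] <- "jointprob_local"
  eset$reason[keep_idx[bad_global & !bad_local]] <- "jointprob_global"
  eset$kept <- eset$reason == "none"
  eset
}

#' Vertical bipolar cEEGrid derivation
#'
#' Collapses an epoch set to the single analysis channel
#' `mean(R2, R3) - mean(R6, R7)`.
#'
#' @param eset An `epoch_set` containing channels R2, R3, R6, R7 (possibly
#'   interpolated).
#' @return An `epoch_set` with one channel labelled `"bipolar"`.
#' @export
derive_bipolar <- function(eset) {
  need <- c("R2", "R3", "R6", "R7")
  if (!all(need %in% eset$labels)) {
    abort(sprintf("channels %s required for the bipolar derivation.",
                  paste(setdiff(need, eset$labels), collapse = ", ")))
  }
  i <- match(need, eset$labels)
  y <- (eset$data[, i[1], , drop = FALSE] + eset$data[, i[2], , drop = FALSE]) / 2 -
    (eset$data[, i[3], , drop = FALSE] + eset$data[, i[4], , drop = FALSE]) / 2
  eset$data <- y
  eset$labels <- "bipolar"
  eset
}

#' Grand-average ERP waveform
#'
#' Averages kept bipolar epochs per role within each epoch set (participant /
#' block), then averages those waveforms across sets with equal weight.
#'
#' @param esets A single bipolar `epoch_set` or a list of them.
#' @return Tibble with `time_s`, `role`, `amplitude`, `n_sets`.
#' @export
grand_average <- function(esets) {
  if (inherits(esets, "epoch_set")) esets <- list(esets)
  purrr::map(esets, function(es) {
    stopifnot(dim(es$data)[2] == 1)
    purrr::map(unique(es$roles[es$kept]), function(r) {
      sel <- es$kept & es$roles == r
      m <- matrix(es$data[sel, 1, , drop = FALSE], nrow = sum(sel))
      tibble(time_s = es$t, role = r, amplitude = colMeans(m))
    }) %>% bind_rows()
  }) %>%
    bind_rows() %>%
    group_by(.data$time_s, .data$role) %>%
    summarise(n_sets = dplyr::n(), amplitude = mean(.data$amplitude),
              .groups = "drop")
}

#' P3 extraction window from a grand-average waveform
#'
#' The window is the latency of the maximum (most positive) grand-average
#' amplitude within the search range, plus/minus the half-width: a peak at
#' 312 ms gives 212--412 ms, a peak at 384 ms gives 284--484 ms. Ties break
#' to the earliest latency; a flat waveform warns.
#'
#' @param grand_avg Tibble with `time_s` and `amplitude` (one role), or a
#'   numeric waveform with a `time_s` attribute.
#' @param search_range_ms Peak search range (ms after stimulus onset).
#' @param halfwidth_ms Half-width of the extraction window (ms).
#' @return A list of class `p3_window`: `peak_latency_ms`, `window_ms`,
#'   `search_range_ms`.
#' @export
#' @examples
#' ga <- tibble::tibble(time_s = seq(0, 0.796, by = 0.004),
#'                      amplitude = dnorm(seq(0, 0.796, by = 0.004), 0.312, 0.07))
#' find_p3_window(ga)$window_ms
find_p3_window <- function(grand_avg, search_range_ms = c(200, 600),
                           halfwidth_ms = 100) {
  t_ms <- grand_avg$time_s * 1000
  a <- grand_avg$amplitude
  sel <- which(t_ms >= search_range_ms[1] & t_ms <= search_range_ms[2])
  if (length(sel) == 0) abort("grand average does not cover the search range.")
  if (diff(range(a[sel])) == 0) {
    warn("flat waveform in the search range; peak tie broken to earliest sample.")
  }
  peak <- t_ms[sel[which.max(a[sel])]]
  structure(
    list(peak_latency_ms = peak,
         window_ms = c(peak - halfwidth_ms, peak + halfwidth_ms),
         search_range_ms = search_range_ms),
    class = "p3_window"
  )
}

#' @export
print.p3_window <- function(x, ...) {
  cat(sprintf("<p3_window> peak %g ms, window %g--%g ms (search %g--%g ms)\n",
              x$peak_latency_ms, x$window_ms[1], x$window_ms[2],
              x$search_range_ms[1], x$search_range_ms[2]))
  invisible(x)
}

#' Per-trial window-mean P3 amplitudes
#'
#' Means of the bipolar samples inside the extraction window, one row per
#' kept epoch.
#'
#' @param eset A bipolar `epoch_set`.
#' @param window A `p3_window` (must lie inside the epoch span).
#' @param participant,condition Identifiers copied into the table (defaults
#'   taken from `eset$meta` when present).
#' @return Tibble with `participant`, `condition`, `role`, `trial`,
#'   `amplitude_uv`.
#' @export
extract_amplitudes <- function(eset, window,
                               participant = eset$meta$participant %||% 1L,
                               condition = eset$meta$variant %||% NA_character_) {
  t_ms <- eset$t * 1000
  if (window$window_ms[1] < min(t_ms) || window$window_ms[2] > max(t_ms)) {
    abort("extraction window lies outside the epoch span.")
  }
  sel <- t_ms >= window$window_ms[1] & t_ms <= window$window_ms[2]
  keep <- which(eset$kept)
  tibble(
    participant = participant, condition = condition,
    role = eset$roles[keep], trial = eset$trial[keep],
    amplitude_uv = rowMeans(eset$data[keep, 1, sel, drop = FALSE][, 1, ,
                                                                  drop = FALSE])
  )
}
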