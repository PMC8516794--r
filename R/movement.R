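#' Gyroscope displacement magnitude
#'
#' Per-sample gross-movement index: the Euclidean norm of the three angular
#' rate axes, `sqrt(yaw^2 + pitch^2 + roll^2)`.
#'
#' @param gyro 3 x samples matrix (or a list with a `gyro` element).
#' @param rate_hz Sampling rate (Hz), for the time base.
#' @param block Optional block label.
#' @return Tibble of class `displacement_series` with `t_s`, `d`, `block`.
#' @export
#' @examples
#' displacement(rbind(3, 4, 0))
displacement <- function(gyro, rate_hz = 250, block = NA) {
  if (is.list(gyro) && !is.null(gyro$gyro)) {
    rate_hz <- gyro$rate %||% rate_hz
    gyro <- gyro$gyro
  }
  if (!is.matrix(gyro) || nrow(gyro) != 3) {
    abort("`gyro` must be a 3 x samples matrix of aligned axes.")
  }
  d <- sqrt(colSums(gyro^2))
  out <- tibble(t_s = (seq_along(d) - 1) / rate_hz, d = d, block = block)
  class(out) <- c("displacement_series", class(out))
  out
}

#' Individual movement-free threshold
#'
#' Median displacement plus four times the interquartile range, computed over
#' the concatenated samples of all supplied rapid blocks (quantiles use the
#' linear-interpolation type-7 convention). Displacement below this value is
#' what is commonly observed while seated, hence "movement-free".
#'
#' @param rapid_blocks A `displacement_series`, a list of them, or a numeric
#'   vector of displacement samples.
#' @param iqr_mult IQR multiplier (default 4).
#' @return One-row tibble: `threshold`, `median_d`, `iqr_d`, `n`.
#' @export
#' @examples
#' individual_threshold(1:100)$threshold  # 50.5 + 4 * 49.5
individual_threshold <- function(rapid_blocks, iqr_mult = 4) {
  d <- if (is.numeric(rapid_blocks)) rapid_blocks
       else if (is.data.frame(rapid_blocks)) rapid_blocks$d
       else unlist(purrr::map(rapid_blocks, "d"))
  if (length(d) == 0) abort("no displacement samples supplied.")
  q <- quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(threshold = q[2] + iqr_mult * (q[3] - q[1]),
         median_d = q[2], iqr_d = q[3] - q[1], n = length(d))
}

#' Fraction of samples below a movement threshold
#'
#' @param series A `displacement_series` (or numeric vector).
#' @param threshold Numeric threshold, or a tibble from
#'   [individual_threshold()].
#' @return Fraction of samples with `d < threshold`.
#' @export
percent_below <- function(series, threshold) {
  d <- if (is.data.frame(series)) series$d else series
  thr <- if (is.data.frame(threshold)) threshold$threshold else threshold
  mean(d < thr)
}

#' Displacement percentile profiles per block
#'
#' For every block, each participant's displacement percentiles (1..99 by
#' default) are computed and then averaged across participants; the global
#' threshold is the mean of the individual thresholds.
#'
#' @param data Tibble with `participant`, `block`, `d` (per-sample rows).
#' @param thresholds Optional tibble with `participant`, `threshold`.
#' @param probs Percentile grid (fractions).
#' @return A list of class `percentile_profile`: `profile` (tibble `block`,
#'   `percentile`, `d`), `global_threshold`.
#' @export
percentile_profile <- function(data, thresholds = NULL,
                               probs = seq(0.01, 0.99, by = 0.01)) {
  if (nrow(data) == 0) abort("no displacement data supplied.")
  prof <- data %>%
    group_by(.data$participant, .data$block) %>%
    dplyr::reframe(percentile = probs * 100,
                   d = quantile(.data$d, probs, names = FALSE, type = 7)) %>%
    group_by(.data$block, .data$percentile) %>%
    summarise(d = mean(.data$d), .groups = "drop")
  structure(
    list(profile = prof,
         global_threshold = if (is.null(thresholds)) NA_real_
                            else mean(thresholds$threshold)),
    class = "percentile_profile"
  )
}

#' Categorized movement time course
#'
#' Each participant's displacement is binned by how many of their rapid-block
#' SDs it sits above their rapid-block mean (0 = within mean + 1 SD, then 1,
#' 2, capped at 3), smoothed with a centered 10-s moving median, resampled to
#' a common 1-Hz clock, and averaged across participants over the span
#' covered by at least half of them.
#'
#' @param data Tibble with `participant`, `t_s`, `d` (a common session clock).
#' @param rapid_stats Tibble with `participant`, `mean_d`, `sd_d` from the
#'   rapid blocks.
#' @param smooth_s Moving-median window (s).
#' @param rate_hz Sampling rate of `data` (Hz).
#' @return A list of class `movement_timecourse`: `per_participant` (tibble
#'   `participant`, `t_s`, `category`), `grand_average` (tibble `t_s`,
#'   `category`, `n`).
#' @export
categorize_timecourse <- function(data, rapid_stats, smooth_s = 10,
                                  rate_hz = 250) {
  per <- data %>%
    left_join(rapid_stats, by = "participant") %>%
    group_by(.data$participant) %>%
    arrange(.data$t_s, .by_group = TRUE) %>%
    mutate(category = {
      if (any(.data$sd_d == 0)) {
        warn("zero rapid-block SD; all samples categorized 0.")
        rep(0, dplyr::n())
      } else {
        pmin(3, floor(pmax(0, (.data$d - .data$mean_d) / .data$sd_d)))
      }
    }) %>%
    mutate(category = moving_median(.data$category,
                                    round(smooth_s * rate_hz))) %>%
    ungroup() %>%
    select("participant", "t_s", "category")

  # common 1-Hz clock; keep seconds covered by at least half the participants
  ga <- per %>%
    mutate(t_s = floor(.data$t_s)) %>%
    group_by(.data$participant, .data$t_s) %>%
    summarise(category = mean(.data$category), .groups = "drop") %>%
    group_by(.data$t_s) %>%
    summarise(n = dplyr::n(), category = mean(.data$category),
              .groups = "drop") %>%
    filter(.data$n >= max(.data$n) / 2)

  structure(list(per_participant = per, grand_average = ga),
            class = "movement_timecourse")
}

#' Centered moving median with edge truncation
#'
#' @param x Numeric vector.
#' @param width Window width in samples (centered; truncated at the edges).
#' @return Smoothed vector, same length.
#' @export
moving_median <- function(x, width) {
  if (width <= 1) return(x)
  half <- floor(width / 2)
  n <- length(x)
  stats::runmed(x, k = 2 * half + 1, endrule = "median")
}

#' Per-participant rapid-block displacement statistics
#'
#' @param data Tibble with `participant`, `d` rows from the rapid blocks.
#' @return Tibble with `participant`, `mean_d`, `sd_d`.
#' @export
rapid_block_stats <- function(data) {
  data %>%
    group_by(.data$participant) %>%
    summarise(mean_d = mean(.data$d), sd_d = sd(.data$d), .groups = "drop")
}
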