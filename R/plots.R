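#' Plot grand-average ERPs
#'
#' Grand-average bipolar waveforms per role (and condition when present),
#' with the P3 extraction window shaded.
#'
#' @param grand_avg Tibble from [grand_average()] (optionally with a
#'   `condition` column).
#' @param window Optional `p3_window` (or named list of them per condition).
#' @return A ggplot object.
#' @export
plot_erp <- function(grand_avg, window = NULL) {
  p <- ggplot2::ggplot(grand_avg,
                       ggplot2::aes(.data$time_s * 1000, .data$amplitude,
                                    linetype = .data$role)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after first-tone onset (ms)",
                  y = "bipolar amplitude (µV)", linetype = NULL) +
    ggplot2::theme_minimal()
  if ("condition" %in% names(grand_avg)) {
    p <- p + ggplot2::facet_wrap(~condition)
  }
  if (!is.null(window)) {
    wins <- if (inherits(window, "p3_window")) list(window) else window
    shade <- purrr::imap(wins, function(w, nm) {
      tibble(xmin = w$window_ms[1], xmax = w$window_ms[2], condition = nm)
    }) %>% bind_rows()
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey50",
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot displacement percentile profiles per block
#'
#' @param x A `percentile_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.percentile_profile <- function(x, ...) {
  p <- ggplot2::ggplot(x$profile,
                       ggplot2::aes(.data$percentile, .data$d,
                                    colour = factor(.data$block))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "percentile", y = "displacement (deg/s)",
                  colour = "block") +
    ggplot2::theme_minimal()
  if (is.finite(x$global_threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = x$global_threshold,
                                 colour = "magenta", linetype = "dashed")
  }
  p
}

#' Plot the grand-average categorized movement time course
#'
#' @param x A `movement_timecourse`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.movement_timecourse <- function(x, ...) {
  ggplot2::ggplot(x$grand_average,
                  ggplot2::aes(.data$t_s / 60, .data$category)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "mean movement category") +
    ggplot2::theme_minimal()
}

#' Plot behavioural summaries per block
#'
#' Mean reaction time (hits) and miss percentage per block across
#' participants.
#'
#' @param behavior Behaviour tibble (e.g. `study$behavior`).
#' @return A ggplot object.
#' @export
plot_behavior <- function(behavior) {
  summ <- behavior %>%
    group_by(.data$participant, .data$block, .data$variant) %>%
    summarise(rt = mean(.data$rt_s, na.rm = TRUE),
              miss_pct = 100 * mean(.data$miss), .groups = "drop") %>%
    tidyr::pivot_longer(c("rt", "miss_pct"), names_to = "measure")
  ggplot2::ggplot(summ, ggplot2::aes(factor(.data$block), .data$value,
                                     fill = .data$variant)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "block", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
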