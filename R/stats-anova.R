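#' One-way repeated-measures ANOVA with generalized eta squared
#'
#' Standard within-subject decomposition for a complete participant x block
#' table of means: `SS_total = SS_subject + SS_block + SS_error`,
#' `F = MS_block / MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of freedom,
#' and `ges = SS_block / (SS_block + SS_subject + SS_error)`. Post hoc
#' pairwise paired t tests over all block pairs are Bonferroni-corrected.
#'
#' @param data Tibble with `participant`, `block`, `value`; one row per cell,
#'   complete (an incomplete table is an error, never silently deleted).
#' @param posthoc Run the pairwise paired t tests.
#' @return A list of class `oddball_anova`: `F`, `df`, `p.value`, `ges`,
#'   `means` (per-block means), `posthoc` (tibble with raw and adjusted p).
#' @export
#' @examples
#' d <- tidyr::expand_grid(participant = 1:4, block = 1:3) %>%
#'   dplyr::mutate(value = block + rnorm(dplyr::n(), 0, 0.1))
#' rm_anova(d)
rm_anova <- function(data, posthoc = TRUE) {
  stopifnot(all(c("participant", "block", "value") %in% names(data)))
  tab <- table(data$participant, data$block)
  if (any(tab != 1)) {
    abort("incomplete or duplicated participant x block cells.")
  }
  n <- length(unique(data$participant))
  k <- length(unique(data$block))
  grand <- mean(data$value)
  m_subj <- data %>% group_by(.data$participant) %>%
    summarise(m = mean(.data$value), .groups = "drop")
  m_block <- data %>% group_by(.data$block) %>%
    summarise(m = mean(.data$value), .groups = "drop")
  ss_subj <- k * sum((m_subj$m - grand)^2)
  ss_block <- n * sum((m_block$m - grand)^2)
  ss_total <- sum((data$value - grand)^2)
  ss_err <- ss_total - ss_subj - ss_block
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_block <- ss_block / df1; ms_err <- ss_err / df2
  f <- if (ms_err <= 0) NaN else ms_block / ms_err
  ges <- if (ss_block + ss_subj + ss_err == 0) 0 else
    ss_block / (ss_block + ss_subj + ss_err)

  ph <- NULL
  if (posthoc && k >= 2) {
    wide <- data %>% arrange(.data$participant) %>%
      tidyr::pivot_wider(names_from = "block", values_from = "value")
    blocks <- as.character(m_block$block)
    pairs <- utils::combn(blocks, 2, simplify = FALSE)
    ph <- purrr::map(pairs, function(pr) {
      tt <- t.test(wide[[pr[1]]], wide[[pr[2]]], paired = TRUE)
      tibble(block_a = pr[1], block_b = pr[2],
             mean_diff = unname(tt$estimate), t = unname(tt$statistic),
             df = unname(tt$parameter), p_raw = tt$p.value)
    }) %>% bind_rows() %>%
      mutate(p_adj = pmin(1, .data$p_raw * dplyr::n()))
  }

  structure(
    list(F = f, df = c(df1, df2),
         p.value = if (is.nan(f)) NaN
                   else stats::pf(f, df1, df2, lower.tail = FALSE),
         ges = ges, means = m_block,
         ss = c(block = ss_block, subject = ss_subj, error = ss_err),
         posthoc = ph),
    class = "oddball_anova"
  )
}

#' @export
print.oddball_anova <- function(x, ...) {
  cat(sprintf("<oddball_anova> F(%d, %d) = %.3f, p = %.4g, ges = %.3f\n",
              x$df[1], x$df[2], x$F, x$p.value, x$ges))
  if (!is.null(x$posthoc)) {
    cat("post hoc paired t tests (Bonferroni):\n")
    print(as.data.frame(x$posthoc), digits = 3)
  }
  invisible(x)
}

#' @rdname rm_anova
#' @param x An `oddball_anova`.
#' @param ... Unused.
#' @export
tidy.oddball_anova <- function(x, ...) {
  tibble(term = "block", statistic = x$F, df1 = x$df[1], df2 = x$df[2],
         p.value = x$p.value, ges = x$ges)
}
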