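#' Simulate a 3-axis gyroscope stream for one block
#'
#' A semi-Markov movement-state process (still / fidget / ambulatory, with
#' exponential dwell times) drives the per-axis angular-rate SD. Rapid blocks
#' draw states from the plan's rapid occupancy (dominated by stillness, as
#' participants were seated at a fixation cross); sporadic blocks use the
#' sporadic occupancy, and at most one sporadic block per session carries a
#' long forced ambulatory "lunch" bout. The calibration segment is always
#' still. Ground-truth state labels are returned per sample.
#'
#' @param config A [session_config()] (uses `gyro_rate_hz`, `calibration_s`,
#'   `activity_plan`).
#' @param duration_s Stream duration (s), normally the matching EEG duration.
#' @param variant `"rapid"` or `"sporadic"`.
#' @param lunch Logical; force the plan's lunch bout into this block.
#' @param seed Optional integer seed.
#' @return List with `gyro` (3 x samples matrix, deg/s), `state` (character
#'   per sample) and `rate`.
#' @export
simulate_gyro <- function(config, duration_s, variant = "rapid",
                          lunch = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  plan <- config$activity_plan
  rate <- config$gyro_rate_hz
  n <- ceiling(duration_s * rate)
  probs <- if (variant == "rapid") plan$rapid_probs else plan$sporadic_probs
  if (lunch) {
    # lunch occupies its own span; draw the remaining time without ambulatory
    probs <- probs * c(1, 1, 0)
  }
  probs <- probs / sum(probs)

  # bout-level state draws: occupancy p with mean dwell d => bout frequency
  # proportional to p / d
  bout_p <- probs / plan$dwell_s
  bout_p <- bout_p / sum(bout_p)
  states <- character(n)
  i <- 1L
  n_cal <- min(n, round(config$calibration_s * rate))
  states[seq_len(n_cal)] <- "still"
  i <- n_cal + 1L
  while (i <= n) {
    s <- sample(names(bout_p), 1, prob = bout_p)
    dwell <- max(1L, round(stats::rexp(1, 1 / plan$dwell_s[[s]]) * rate))
    j <- min(n, i + dwell - 1L)
    states[i:j] <- s
    i <- j + 1L
  }
  if (lunch) {
    i0 <- n_cal + round(plan$lunch_fraction[["start"]] * (n - n_cal))
    i1 <- min(n, i0 + round(plan$lunch_fraction[["duration"]] * (n - n_cal)))
    states[i0:i1] <- "ambulatory"
  }

  sds <- c(still = plan$still_sd,
           fidget = plan$still_sd * plan$fidget_gain,
           ambulatory = plan$still_sd * plan$ambulatory_gain)
  sd_per_sample <- sds[states]
  gyro <- rbind(
    rnorm(n, 0, sd_per_sample),
    rnorm(n, 0, sd_per_sample),
    rnorm(n, 0, sd_per_sample)
  )
  rownames(gyro) <- c("yaw", "pitch", "roll")
  list(gyro = gyro, state = states, rate = rate)
}
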