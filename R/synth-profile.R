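#' Generative participant profile
#'
#' Bundles the link-scale generative truth for one simulated participant:
#' reaction-time GLMM coefficients (inverse-Gaussian family, inverse link, so
#' the response-scale mean is `1 / eta`), miss GLMM coefficients (binomial,
#' logit link), ERP amplitudes on the vertical bipolar cEEGrid channel, P3 peak
#' latencies per oddball variant, and the background-noise level.
#'
#' Defaults are the fitted values of the reference day-long ear-EEG oddball
#' study: rapid-condition mean RT 1/0.91 ~ 1.10 s, sporadic 1/(0.91-0.39) ~
#' 1.92 s; rapid miss chance plogis(-3.31) ~ 3.5%, sporadic plogis(-2.16) ~
#' 10.3%; bipolar P3 window means 1.07 uV (standard) + 1.75 uV (target
#' increase) in the rapid condition and 1.63 + 1.20 uV in the sporadic
#' condition, with peak latencies 312 and 384 ms.
#'
#' @param rt_intercept_link,rt_slope_link RT fixed effects on the inverse-link
#'   scale (1/s); the slope is the sporadic-minus-rapid change.
#' @param rt_random_sds Length-2 SDs of the independent by-participant random
#'   intercept and slope (link scale).
#' @param rt_shape Inverse-Gaussian shape parameter `lambda` (variance is
#'   `mu^3 / lambda`).
#' @param miss_intercept_link,miss_slope_link Miss fixed effects (logit scale).
#' @param miss_random_sds Length-2 SDs of the independent random intercept and
#'   slope (logit scale).
#' @param erp_standard_uv,erp_target_delta_uv Named vectors (`rapid`,
#'   `sporadic`): window-mean bipolar amplitude of standard epochs and the
#'   target increase, in microvolts.
#' @param erp_peak_rapid_ms,erp_peak_sporadic_ms P3 peak latency (ms).
#' @param noise_uv_rms RMS of the 1/f background noise per channel (uV).
#'
#' @return A list of class `participant_profile`.
#' @export
participant_profile <- function(rt_intercept_link = 0.91,
                                rt_slope_link = -0.39,
                                rt_random_sds = c(0.05, 0.05),
                                rt_shape = 6.9,
                                miss_intercept_link = -3.31,
                                miss_slope_link = 1.15,
                                miss_random_sds = c(0.25, 0.25),
                                erp_standard_uv = c(rapid = 1.07, sporadic = 1.63),
                                erp_target_delta_uv = c(rapid = 1.75, sporadic = 1.20),
                                erp_peak_rapid_ms = 312,
                                erp_peak_sporadic_ms = 384,
                                noise_uv_rms = 4) {
  stopifnot(rt_shape > 0, length(rt_random_sds) == 2, length(miss_random_sds) == 2)
  if (rt_intercept_link <= 0 || rt_intercept_link + rt_slope_link <= 0) {
    abort("link-scale RT predictors must be positive (inverse link).")
  }
  structure(
    list(
      rt_intercept_link = rt_intercept_link, rt_slope_link = rt_slope_link,
      rt_random_sds = rt_random_sds, rt_shape = rt_shape,
      miss_intercept_link = miss_intercept_link,
      miss_slope_link = miss_slope_link, miss_random_sds = miss_random_sds,
      erp_standard_uv = erp_standard_uv,
      erp_target_delta_uv = erp_target_delta_uv,
      erp_peak_rapid_ms = erp_peak_rapid_ms,
      erp_peak_sporadic_ms = erp_peak_sporadic_ms,
      noise_uv_rms = noise_uv_rms
    ),
    class = "participant_profile"
  )
}

#' Session configuration for the synthetic generator
#'
#' @param n_participants Number of simulated participants.
#' @param block_plan Ordered character vector of block variants; the default is
#'   the day plan rapid/sporadic/rapid/sporadic/rapid.
#' @param eeg_rate_hz EEG sampling rate (Hz).
#' @param gyro_rate_hz Gyroscope sampling rate (Hz; shares the EEG clock).
#' @param channel_labels cEEGrid channel labels; must contain R2, R3, R6, R7
#'   for the vertical bipolar derivation.
#' @param calibration_s Artifact-free calibration segment prepended to every
#'   block (s).
#' @param n_trials,target_fraction Scored-trial composition per block.
#' @param activity_plan Movement-state parameters, see [default_activity_plan()].
#'
#' @return A list of class `session_config`.
#' @export
session_config <- function(n_participants = 8,
                           block_plan = c("rapid", "sporadic", "rapid",
                                          "sporadic", "rapid"),
                           eeg_rate_hz = 250,
                           gyro_rate_hz = 250,
                           channel_labels = ceegrid_labels(),
                           calibration_s = 60,
                           n_trials = 160,
                           target_fraction = 0.3,
                           activity_plan = default_activity_plan()) {
  stopifnot(all(block_plan %in% c("rapid", "sporadic")),
            all(c("R2", "R3", "R6", "R7") %in% channel_labels))
  structure(
    list(
      n_participants = n_participants, block_plan = block_plan,
      eeg_rate_hz = eeg_rate_hz, gyro_rate_hz = gyro_rate_hz,
      channel_labels = channel_labels, calibration_s = calibration_s,
      n_trials = n_trials, target_fraction = target_fraction,
      activity_plan = activity_plan
    ),
    class = "session_config"
  )
}

#' Default cEEGrid channel label set
#'
#' Two 10-electrode C-shaped grids; R4a (driven right leg) and R4b (reference)
#' do not yield signal channels, leaving 18 recorded channels.
#'
#' @return Character vector of 18 labels.
#' @export
ceegrid_labels <- function() {
  c(paste0("L", c("1", "2", "3", "4a", "4b", "5", "6", "7", "8", "9")),
    paste0("R", c("1", "2", "3", "5", "6", "7", "8", "9")))
}

#' Approximate cEEGrid electrode coordinates on the unit sphere
#'
#' Fixed synthetic positions for spherical-spline interpolation: each grid is a
#' C-shaped arc around the ear, mapped to a small ring of directions around the
#' left/right temporal poles of a unit head sphere. These are idealized
#' stand-in coordinates (the grids' true digitized positions are not part of
#' the package).
#'
#' @param labels Channel labels to return coordinates for.
#' @return Tibble with `label`, `x`, `y`, `z` (unit norm).
#' @export
ceegrid_coords <- function(labels = ceegrid_labels()) {
  one_side <- function(side) {
    labs <- grep(paste0("^", side), labels, value = TRUE)
    k <- length(labs)
    # arc from above the ear, around the back, to below the ear
    ang <- seq(80, 280, length.out = k) * pi / 180
    r <- 0.35                       # arc radius on the sphere surface
    pole_y <- if (side == "L") 1 else -1
    # local tangent-plane circle around the temporal pole, then renormalize
    px <- r * cos(ang)              # anterior-posterior offset
    pz <- r * sin(ang)              # inferior-superior offset
    y <- pole_y * sqrt(pmax(0, 1 - px^2 - pz^2))
    tibble(label = labs, x = px, y = y, z = pz)
  }
  bind_rows(one_side("L"), one_side("R")) %>%
    filter(.data$label %in% labels)
}

#' Default movement-state plan
#'
#' Three semi-Markov states with exponential dwell times: `still` (baseline
#' sensor noise), `fidget` (short posture shifts), `ambulatory` (walking).
#' Rapid blocks are dominated by stillness; sporadic blocks mix states and the
#' final sporadic block carries one long ambulatory "lunch" bout.
#'
#' @param still_sd Per-axis angular-rate SD (deg/s) while still.
#' @param fidget_gain,ambulatory_gain Multiplier on `still_sd` for the other
#'   states.
#' @param rapid_probs,sporadic_probs State occupancy probabilities
#'   (still/fidget/ambulatory) used for state sequencing.
#' @param dwell_s Mean dwell time per state (s).
#' @param lunch_fraction Fractional (start, duration) of the lunch bout within
#'   the designated sporadic block.
#' @return A list of class `activity_plan`.
#' @export
default_activity_plan <- function(still_sd = 1,
                                  fidget_gain = 6,
                                  ambulatory_gain = 12,
                                  rapid_probs = c(still = 0.95, fidget = 0.05,
                                                  ambulatory = 0),
                                  sporadic_probs = c(still = 0.75, fidget = 0.13,
                                                     ambulatory = 0.12),
                                  dwell_s = c(still = 30, fidget = 4,
                                              ambulatory = 20),
                                  lunch_fraction = c(start = 0.35,
                                                     duration = 0.2)) {
  structure(
    list(still_sd = still_sd, fidget_gain = fidget_gain,
         ambulatory_gain = ambulatory_gain,
         rapid_probs = rapid_probs, sporadic_probs = sporadic_probs,
         dwell_s = dwell_s, lunch_fraction = lunch_fraction),
    class = "activity_plan"
  )
}
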