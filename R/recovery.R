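#' Simulation-refit recovery of the behavioural models
#'
#' Generates behaviour for `n_participants` simulated participants under the
#' full five-block day plan (3 rapid + 2 sporadic blocks, 48 scored targets
#' each) from the profile's generative reaction-time and miss models, refits
#' both GLMMs, and repeats. The averaged response-scale summaries estimate
#' how well the fitted models recover the generative truth.
#'
#' @param n_reps Number of replicates.
#' @param profile A [participant_profile()] holding the generative truth.
#' @param n_participants Participants per replicate.
#' @param seed Integer seed for the whole run.
#' @param progress Print a dot per replicate.
#' @return Tibble with one row per replicate: `rt_rapid_s`, `rt_sporadic_s`,
#'   `rt_increase_s`, `miss_rapid_pct`, `miss_sporadic_pct`,
#'   `rt_slope_p`, `miss_slope_p`.
#' @export
recover_behavior <- function(n_reps = 100, profile = participant_profile(),
                             n_participants = 8, seed = 1, progress = FALSE) {
  set.seed(seed)
  purrr::map(seq_len(n_reps), function(r) {
    sch <- purrr::imap(
      c("rapid", "sporadic", "rapid", "sporadic", "rapid"),
      function(v, b) generate_schedule(v)
    )
    names(sch) <- paste0("b", seq_along(sch))
    beh <- purrr::map(seq_len(n_participants), function(p) {
      simulate_behavior(profile, sch, participant = p)
    }) %>% bind_rows()

    rt_fit <- fit_glmm(filter(beh, !.data$miss), "rt_s", "variant",
                       family = "inverse_gaussian", link = "inverse")
    beh$miss_num <- as.numeric(beh$miss)
    miss_fit <- fit_glmm(beh, "miss_num", "variant", family = "binomial")

    if (progress) cat(".")
    rs <- rt_fit$response_scale$mean_response
    ms <- miss_fit$response_scale$mean_response
    tibble(
      rep = r,
      rt_rapid_s = rs[1], rt_sporadic_s = rs[2], rt_increase_s = rs[2] - rs[1],
      miss_rapid_pct = 100 * ms[1], miss_sporadic_pct = 100 * ms[2],
      rt_slope_p = wald_chisq(rt_fit, "sporadic")$p.value,
      miss_slope_p = wald_chisq(miss_fit, "sporadic")$p.value
    )
  }) %>% bind_rows()
}

#' Simulation-refit recovery of the ERP amplitude model
#'
#' Two levels of fidelity. `level = "amplitude"` simulates per-trial P3
#' window-mean amplitudes directly from the generative LMM (fixed standard
#' mean + target increase, independent by-participant random intercept and
#' slope, Gaussian trial noise) and refits the LMM. `level = "pipeline"` runs
#' the whole ERP chain instead: continuous EEG synthesis, epoching with
#' exclusions, joint-probability rejection, bipolar derivation,
#' grand-average P3 window search, per-trial amplitude extraction, then the
#' LMM.
#'
#' @param n_reps Number of replicates (pipeline level: seeds).
#' @param condition `"rapid"` or `"sporadic"`.
#' @param profile Generative [participant_profile()].
#' @param n_participants Participants per replicate.
#' @param level `"amplitude"` or `"pipeline"`.
#' @param n_trials Scored trials per block at pipeline level (the sporadic
#'   default is reduced because a full sporadic block spans 160 min of
#'   continuous signal; the ISI distribution itself is kept).
#' @param re_sds Between-participant SDs (intercept, slope) for the
#'   amplitude-level generative model (uV).
#' @param jointprob Run the joint-probability rejection stage at pipeline
#'   level. Disabling it gives the pure construction oracle: the rejection
#'   rule preferentially trims extreme target epochs on strongly bimodal
#'   synthetic data and attenuates the fitted contrast by a few percent.
#' @param resid_sd Trial-level Gaussian noise SD at amplitude level (uV).
#' @param seed Integer seed.
#' @param progress Print a dot per replicate.
#' @return Tibble per replicate: `standard_uv` (fitted standard mean),
#'   `delta_uv` (fitted target increase), `peak_ms` (pipeline level only),
#'   `slope_p`.
#' @export
recover_erp <- function(n_reps = 100, condition = c("rapid", "sporadic"),
                        profile = participant_profile(), n_participants = 8,
                        level = c("amplitude", "pipeline"),
                        n_trials = if (condition == "rapid") 160 else 24,
                        re_sds = c(0.3, 0.3), resid_sd = 3,
                        jointprob = TRUE, seed = 1, progress = FALSE) {
  condition <- match.arg(condition)
  level <- match.arg(level)
  set.seed(seed)
  mu_std <- profile$erp_standard_uv[[condition]]
  delta <- profile$erp_target_delta_uv[[condition]]

  purrr::map(seq_len(n_reps), function(r) {
    if (level == "amplitude") {
      amp <- purrr::map(seq_len(n_participants), function(p) {
        u0 <- rnorm(1, 0, re_sds[1]); u1 <- rnorm(1, 0, re_sds[2])
        roles <- rep(c("standard", "target"), c(112, 48))
        mu <- mu_std + u0 + (delta + u1) * (roles == "target")
        tibble(participant = p, condition = condition, role = roles,
               trial = seq_along(roles),
               amplitude_uv = rnorm(length(roles), mu, resid_sd))
      }) %>% bind_rows()
      peak <- NA_real_
    } else {
      cfg <- session_config(
        n_participants = n_participants, block_plan = condition,
        channel_labels = c("R2", "R3", "R6", "R7"),
        n_trials = n_trials
      )
      esets <- purrr::map(seq_len(n_participants), function(p) {
        sch <- generate_schedule(condition, n_trials = n_trials)
        rec <- simulate_eeg(profile, sch, cfg, participant = p)
        beh <- simulate_behavior(profile, list(b1 = sch), participant = p)
        es <- extract_epochs(rec, beh)
        if (jointprob) es <- reject_jointprob(es)
        derive_bipolar(es)
      })
      ga <- grand_average(esets) %>%
        group_by(.data$time_s) %>%
        summarise(amplitude = mean(.data$amplitude), .groups = "drop")
      win <- find_p3_window(ga)
      peak <- win$peak_latency_ms
      amp <- purrr::imap(esets, function(es, p) {
        extract_amplitudes(es, win, participant = p, condition = condition)
      }) %>% bind_rows()
    }
    fit <- fit_glmm(amp, "amplitude_uv", "role", family = "gaussian")
    if (progress) cat(".")
    tibble(rep = r,
           standard_uv = fit$beta_link[["intercept"]],
           delta_uv = fit$beta_link[["target"]],
           peak_ms = peak,
           slope_p = wald_chisq(fit, "target")$p.value)
  }) %>% bind_rows()
}

#' Monte-Carlo summary of a recovery run
#'
#' Mean, Monte-Carlo SE (SD / sqrt(reps)) and the recovered-vs-truth
#' difference in MC-SE units for one recovery column.
#'
#' @param draws Numeric vector of per-replicate estimates.
#' @param truth Generative value.
#' @return One-row tibble: `mean`, `mc_se`, `truth`, `z`.
#' @export
recovery_summary <- function(draws, truth) {
  m <- mean(draws); se <- sd(draws) / sqrt(length(draws))
  tibble(mean = m, mc_se = se, truth = truth, z = (m - truth) / se)
}
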