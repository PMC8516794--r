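#' Run the full analysis over a set of simulated participants
#'
#' End-to-end driver: simulates (or accepts) one session per participant,
#' optionally runs the continuous cleaning chain on every block, then the ERP
#' chain (epoching with exclusions, joint-probability rejection, bipolar
#' derivation, per-condition grand-average P3 windows, per-trial
#' amplitudes), the behavioural GLMMs, the ERP LMM per condition, and the
#' movement analysis (displacement, individual thresholds, movement-free
#' fractions, per-block RM-ANOVA, percentile profiles, categorized time
#' course).
#'
#' @param profile Generative [participant_profile()].
#' @param config A [session_config()].
#' @param pipeline [pipeline_config()] stage parameters.
#' @param seed Integer seed; participant `p` uses `seed + p`.
#' @param clean Run the continuous cleaning chain (filters, ASR, channel
#'   rejection/interpolation) before epoching. With artifact-free synthetic
#'   sessions this can be disabled to save time.
#' @param artifact_plans Passed to [simulate_session()].
#' @param sessions Optional pre-simulated list of `oddball_session`s
#'   (overrides simulation).
#' @return A list of class `oddball_study` with elements `amplitudes`,
#'   `windows`, `grand_averages`, `behavior`, `fits` (`rt`, `miss`,
#'   `erp_rapid`, `erp_sporadic`), `movement` (`thresholds`,
#'   `block_summary`, `anova`, `profile`, `timecourse`), `rejections`,
#'   `manifest`.
#' @export
run_study <- function(profile = participant_profile(),
                      config = session_config(),
                      pipeline = pipeline_config(),
                      seed = 1, clean = FALSE, artifact_plans = NULL,
                      sessions = NULL) {
  if (is.null(sessions)) {
    sessions <- purrr::map(seq_len(config$n_participants), function(p) {
      simulate_session(profile, config, participant = p,
                       artifact_plans = artifact_plans, seed = seed + p)
    })
  }

  esets <- list(); rejections <- list(); discarded <- list()
  disp <- list()
  for (s in sessions) {
    for (b in seq_along(s$recordings)) {
      rec <- s$recordings[[b]]
      variant <- rec$meta$variant
      key <- sprintf("p%s_b%d", s$participant, b)
      if (clean) {
        cl <- clean_recording(rec, pipeline)
        rejections[[key]] <- cl$report
        if (cl$report$block_discarded) {
          discarded[[key]] <- cl$report$reason
          next
        }
        rec <- cl$recording
      }
      beh <- filter(s$behavior, .data$block == as.character(b) |
                      .data$block == b)
      es <- extract_epochs(rec, beh, pipeline$epoch_span_s,
                           pipeline$baseline_s)
      es <- reject_jointprob(es, pipeline$jointprob_z)
      es <- derive_bipolar(es)
      es$meta$key <- key
      esets[[key]] <- es
      if (!is.null(rec$gyro)) {
        dd <- displacement(rec$gyro, rec$gyro_rate, block = b)
        dd$participant <- s$participant
        dd$variant <- variant
        disp[[key]] <- dd
      }
    }
  }

  variants <- purrr::map_chr(esets, ~ .x$meta$variant)
  windows <- list(); gas <- list(); amps <- list()
  for (v in unique(variants)) {
    sub <- esets[variants == v]
    ga <- grand_average(sub)
    ga_pooled <- ga %>% group_by(.data$time_s) %>%
      summarise(amplitude = mean(.data$amplitude), .groups = "drop")
    win <- find_p3_window(ga_pooled,
                          pipeline$p3_search_ms, pipeline$p3_halfwidth_ms)
    gas[[v]] <- mutate(ga, condition = v)
    windows[[v]] <- win
    amps[[v]] <- purrr::map(sub, function(es) {
      extract_amplitudes(es, win, participant = es$meta$participant,
                         condition = v)
    }) %>% bind_rows()
  }
  amplitudes <- bind_rows(amps)

  behavior <- purrr::map(sessions, "behavior") %>% bind_rows()
  behavior$miss_num <- as.numeric(behavior$miss)
  fits <- list()
  if (length(unique(behavior$variant)) == 2) {
    fits$rt <- fit_glmm(filter(behavior, !.data$miss), "rt_s", "variant",
                        family = "inverse_gaussian")
    if (var(behavior$miss_num) > 0) {
      fits$miss <- fit_glmm(behavior, "miss_num", "variant",
                            family = "binomial")
    }
  }
  for (v in names(windows)) {
    fits[[paste0("erp_", v)]] <-
      fit_glmm(filter(amplitudes, .data$condition == v), "amplitude_uv",
               "role", family = "gaussian")
  }

  movement <- NULL
  if (length(disp)) {
    dall <- bind_rows(disp)
    thr <- dall %>% filter(.data$variant == "rapid") %>%
      group_by(.data$participant) %>%
      summarise(individual_threshold(.data$d), .groups = "drop")
    block_summary <- dall %>%
      left_join(select(thr, "participant", "threshold"), by = "participant") %>%
      group_by(.data$participant, .data$block, .data$variant) %>%
      summarise(mean_d = mean(.data$d),
                frac_below = mean(.data$d < .data$threshold),
                .groups = "drop")
    anova <- NULL
    if (length(unique(block_summary$block)) >= 2 &&
        length(unique(block_summary$participant)) >= 2) {
      anova <- rm_anova(block_summary %>%
                          select("participant", "block", value = "mean_d"))
    }
    prof <- percentile_profile(dall, thr)
    rstats <- rapid_block_stats(filter(dall, .data$variant == "rapid"))
    tc <- categorize_timecourse(
      dall %>% select("participant", "t_s", "d"), rstats,
      smooth_s = pipeline$smooth_s,
      rate_hz = sessions[[1]]$recordings[[1]]$gyro_rate
    )
    movement <- list(thresholds = thr, block_summary = block_summary,
                     anova = anova, profile = prof, timecourse = tc)
  }

  manifest <- tibble(
    key = names(esets),
    participant = purrr::map_chr(esets, ~ as.character(.x$meta$participant)),
    variant = variants,
    n_epochs = purrr::map_int(esets, ~ length(.x$kept)),
    n_kept = purrr::map_int(esets, ~ sum(.x$kept)),
    seed = seed
  )

  structure(
    list(amplitudes = amplitudes, windows = windows,
         grand_averages = bind_rows(gas), behavior = behavior, fits = fits,
         movement = movement, rejections = rejections,
         discarded = discarded, manifest = manifest,
         config = config, pipeline = pipeline, seed = seed),
    class = "oddball_study"
  )
}

#' @export
print.oddball_study <- function(x, ...) {
  cat(sprintf("<oddball_study> %d analysed blocks, %d discarded; seed %s\n",
              nrow(x$manifest), length(x$discarded), x$seed))
  for (v in names(x$windows)) {
    cat(sprintf("  %s P3 window: %g--%g ms (peak %g ms)\n", v,
                x$windows[[v]]$window_ms[1], x$windows[[v]]$window_ms[2],
                x$windows[[v]]$peak_latency_ms))
  }
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s=%.3f", f$response_scale$level,
                              f$response_scale$mean_response),
                      collapse = ", ")))
  }
  invisible(x)
}
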