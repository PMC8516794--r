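test_that("behavioural generator matches its closed forms without random effects", {
  prof <- quiet_profile()
  sch <- lapply(1:20, function(s) generate_schedule("rapid", seed = s))
  names(sch) <- seq_along(sch)
  set.seed(42)
  beh <- simulate_behavior(prof, sch, random_effects = list(rt = c(0, 0),
                                                            miss = c(0, 0)))
  n <- nrow(beh)                      # 20 x 48 targets
  p_true <- stats::plogis(-3.31)      # rapid miss chance 3.5%
  expect_lt(abs(mean(beh$miss) - p_true), 3 * sqrt(p_true * (1 - p_true) / n))

  rts <- beh$rt_s[!beh$miss]
  mu <- 1 / 0.91                      # inverse link: mean 1.099 s
  sd_ig <- sqrt(mu^3 / 6.9)
  expect_lt(abs(mean(rts) - mu), 3 * sd_ig / sqrt(length(rts)))
  expect_true(all(rts > 0))
})

test_that("zero condition slope leaves rapid and sporadic RTs exchangeable", {
  prof <- participant_profile(rt_slope_link = 0, miss_slope_link = 0,
                              rt_random_sds = c(0, 0),
                              miss_random_sds = c(0, 0), noise_uv_rms = 0)
  sch <- list(a = generate_schedule("rapid", seed = 1),
              b = generate_schedule("sporadic", seed = 2))
  set.seed(7)
  beh <- dplyr::bind_rows(lapply(1:15, function(p)
    simulate_behavior(prof, sch, participant = p)))
  ks <- suppressWarnings(
    stats::ks.test(beh$rt_s[beh$variant == "rapid" & !beh$miss],
                   beh$rt_s[beh$variant == "sporadic" & !beh$miss]))
  expect_gt(ks$p.value, 0.01)
})

test_that("inverse-Gaussian sampler matches theoretical moments", {
  set.seed(1)
  x <- rinvgauss(20000, mu = 1.5, lambda = 5)
  expect_equal(mean(x), 1.5, tolerance = 0.02)
  expect_equal(var(x), 1.5^3 / 5, tolerance = 0.05)
  expect_true(all(x > 0))
})

test_that("noise-free EEG reproduces the configured bipolar window means exactly", {
  prof <- quiet_profile()
  cfg <- bipolar_config(n_trials = 8)
  sch <- generate_schedule("rapid", n_trials = 8, target_fraction = 0.25,
                           seed = 5)
  rec <- simulate_eeg(prof, sch, cfg, seed = 5)
  es <- derive_bipolar(extract_epochs(rec))
  win <- find_p3_window(
    tibble::tibble(time_s = es$t,
                   amplitude = colMeans(matrix(es$data[es$kept, 1, ],
                                               nrow = sum(es$kept)))))
  expect_equal(win$peak_latency_ms, 312)
  amp <- extract_amplitudes(es, win)
  expect_equal(amp$amplitude_uv[amp$role == "standard"],
               rep(1.07, sum(amp$role == "standard")), tolerance = 1e-10)
  expect_equal(amp$amplitude_uv[amp$role == "target"],
               rep(1.07 + 1.75, sum(amp$role == "target")), tolerance = 1e-10)
})

test_that("grand-average peak latency lands on the generative latency", {
  # full-size grand average: 8 participants x 160 rapid trials at the default
  # 4 uV 1/f background
  r <- recover_erp(n_reps = 2, condition = "rapid", level = "pipeline",
                   seed = 31)
  expect_true(all(abs(r$peak_ms - 312) <= 8))   # within 2 samples at 250 Hz
})

test_that("sessions are seed-deterministic", {
  cfg <- bipolar_config(n_trials = 6)
  s1 <- simulate_session(participant_profile(), cfg, seed = 99)
  s2 <- simulate_session(participant_profile(), cfg, seed = 99)
  expect_identical(s1$recordings[[1]]$eeg, s2$recordings[[1]]$eeg)
  expect_identical(s1$recordings[[1]]$gyro, s2$recordings[[1]]$gyro)
  expect_identical(s1$behavior, s2$behavior)
})

test_that("artifact injection is logged completely and an empty plan is identity", {
  cfg <- session_config(block_plan = "rapid", n_trials = 80,
                        calibration_s = 30)
  ses <- simulate_session(participant_profile(), cfg, seed = 12)
  rec <- ses$recordings[[1]]

  out0 <- inject_artifacts(rec, empty_artifact_plan(), seed = 1)
  expect_identical(out0$recording$eeg, rec$eeg)
  expect_equal(nrow(out0$log), 0)

  plan <- artifact_plan(
    burst_rate_per_min = 2,
    flatline = tibble::tibble(channel = "L5", start_s = 40, dur_s = 120),
    noisy = tibble::tibble(channel = "R8", gain = 10),
    transient_rate_per_min = 1)
  out <- inject_artifacts(rec, plan, seed = 2)
  log <- out$log

  # the log locates every insertion
  expect_setequal(unique(log$kind[log$kind %in% c("flatline", "noisy")]),
                  c("flatline", "noisy"))
  fl <- log[log$kind == "flatline", ]
  expect_equal(fl$channel, "L5")
  expect_equal(detect_flatlines(out$recording, 60), "L5")
  for (k in which(log$kind == "burst")) {
    i0 <- round(log$start_s[k] * rec$rate); i1 <- round(log$end_s[k] * rec$rate)
    expect_gt(sqrt(mean(out$recording$eeg[, i0:i1]^2)),
              2 * sqrt(mean(rec$eeg[, i0:i1]^2)))
  }
  # flatline window exceeding the span errors
  bad <- artifact_plan(flatline = tibble::tibble(channel = "L1",
                                                 start_s = 1e4, dur_s = 60))
  expect_error(inject_artifacts(rec, bad), "span")
})

test_that("gyroscope states order displacement and stillness is exact at zero noise", {
  cfg <- session_config(block_plan = "rapid",
                        activity_plan = default_activity_plan(still_sd = 0))
  g0 <- simulate_gyro(cfg, duration_s = 70, variant = "rapid", seed = 1)
  expect_true(all(displacement(g0$gyro)$d == 0))

  cfg2 <- session_config(block_plan = "sporadic")
  g <- simulate_gyro(cfg2, duration_s = 200, variant = "sporadic",
                     lunch = TRUE, seed = 2)
  d <- displacement(g$gyro)$d
  means <- tapply(d, g$state, mean)
  expect_true(means[["ambulatory"]] > means[["fidget"]])
  expect_true(means[["fidget"]] > means[["still"]])
})
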