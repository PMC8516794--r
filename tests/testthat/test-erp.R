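test_that("epochs span 250 samples, are baseline-zeroed, and log exclusions", {
  prof <- quiet_profile()
  cfg <- bipolar_config(n_trials = 12)
  sch <- generate_schedule("rapid", n_trials = 12, seed = 8)
  rec <- simulate_eeg(prof, sch, cfg, seed = 8)

  # constant channel offset disappears after baseline correction
  rec$eeg[1, ] <- rec$eeg[1, ] + 13.7
  es <- extract_epochs(rec)
  expect_equal(dim(es$data)[3], 250)
  expect_equal(es$t[1], -0.2)
  base <- es$t < 0
  expect_lt(max(abs(apply(es$data[es$kept, , base, drop = FALSE], 1:2, mean))),
            1e-9)
  expect_equal(sum(es$reason == "first_two"), 2)

  # misses flagged from the behaviour table
  tg <- sch$trial[sch$role == "target"][1:3]
  beh <- tibble::tibble(trial = tg, miss = TRUE)
  es2 <- extract_epochs(rec, beh)
  expect_equal(sum(es2$reason == "missed_target"), 3)
})

test_that("joint-probability rejection finds planted outliers and nothing else", {
  set.seed(9)
  n_ep <- 100
  data <- array(rnorm(n_ep * 2 * 50), c(n_ep, 2, 50))
  data[37, , ] <- data[37, , ] * 10
  es <- make_epoch_set(data, roles = rep("standard", n_ep))
  out <- reject_jointprob(es, 2)
  expect_equal(which(!out$kept), 37)

  # identical epochs: no rejections
  same <- array(rep(sin(1:50), each = 20), c(20, 1, 50))
  es_same <- make_epoch_set(same, roles = rep("standard", 20))
  expect_true(all(reject_jointprob(es_same)$kept))

  # rejection rate decreases monotonically in the threshold
  set.seed(10)
  noisy <- array(rnorm(200 * 1 * 50), c(200, 1, 50))
  esn <- make_epoch_set(noisy, roles = rep("standard", 200))
  rates <- sapply(c(1, 1.5, 2, 3), function(z)
    mean(!reject_jointprob(esn, z)$kept))
  expect_true(all(diff(rates) <= 0))
})

test_that("bipolar derivation is the R2/R3 minus R6/R7 contrast", {
  data <- array(0, c(3, 4, 10))
  data[, 1, ] <- 2; data[, 2, ] <- 2       # R2 R3
  data[, 3, ] <- 1; data[, 4, ] <- 1       # R6 R7
  es <- make_epoch_set(data, roles = rep("standard", 3),
                       labels = c("R2", "R3", "R6", "R7"))
  bp <- derive_bipolar(es)
  expect_equal(dim(bp$data)[2], 1)
  expect_true(all(bp$data == 1))

  # +a upper / -a lower loadings double into the contrast
  tpl <- sin(seq(0, pi, length.out = 10))
  a <- 0.7
  d2 <- array(0, c(2, 4, 10))
  for (e in 1:2) {
    d2[e, 1, ] <- a * tpl; d2[e, 2, ] <- a * tpl
    d2[e, 3, ] <- -a * tpl; d2[e, 4, ] <- -a * tpl
  }
  es2 <- make_epoch_set(d2, roles = rep("target", 2),
                        labels = c("R2", "R3", "R6", "R7"))
  expect_equal(derive_bipolar(es2)$data[1, 1, ], 2 * a * tpl)

  es_miss <- make_epoch_set(data[, 1:3, , drop = FALSE],
                            roles = rep("standard", 3),
                            labels = c("R2", "R3", "R6"))
  expect_error(derive_bipolar(es_miss), "R7")
})

test_that("the P3 window rule reproduces the published windows", {
  t_s <- seq(0, 0.8, by = 0.004)
  ga <- function(peak_ms) tibble::tibble(
    time_s = t_s, amplitude = exp(-(t_s * 1000 - peak_ms)^2 / (2 * 70^2)))
  w1 <- find_p3_window(ga(312))
  expect_equal(w1$peak_latency_ms, 312)
  expect_equal(w1$window_ms, c(212, 412))
  w2 <- find_p3_window(ga(384))
  expect_equal(w2$window_ms, c(284, 484))
  expect_equal(diff(w1$window_ms), 200)

  # global maximum outside the search range is ignored
  amp <- exp(-(t_s * 1000 - 400)^2 / (2 * 50^2)) +
    3 * exp(-(t_s * 1000 - 700)^2 / (2 * 20^2))
  w3 <- find_p3_window(tibble::tibble(time_s = t_s, amplitude = amp))
  expect_equal(w3$peak_latency_ms, 400)

  expect_warning(
    find_p3_window(tibble::tibble(time_s = t_s, amplitude = rep(1, length(t_s)))),
    "flat")
})

test_that("window means are exact on constructed epochs and bounded windows", {
  data <- array(1, c(5, 1, 250))
  es <- make_epoch_set(data, roles = rep("standard", 5), labels = "bipolar")
  win <- find_p3_window(tibble::tibble(time_s = es$t,
                                       amplitude = dnorm(es$t, 0.312, 0.07)))
  amp <- extract_amplitudes(es, win)
  expect_equal(amp$amplitude_uv, rep(1, 5))

  far <- structure(list(peak_latency_ms = 900, window_ms = c(800, 1000),
                        search_range_ms = c(200, 600)), class = "p3_window")
  expect_error(extract_amplitudes(es, far), "outside")
})

test_that("averaging then windowing commutes with windowing then averaging", {
  set.seed(11)
  data <- array(rnorm(30 * 1 * 250), c(30, 1, 250))
  es <- make_epoch_set(data, roles = rep("target", 30), labels = "bipolar")
  win <- structure(list(peak_latency_ms = 312, window_ms = c(212, 412),
                        search_range_ms = c(200, 600)), class = "p3_window")
  amp <- extract_amplitudes(es, win)
  ga <- grand_average(es)
  sel <- ga$time_s * 1000 >= 212 & ga$time_s * 1000 <= 412
  expect_equal(mean(amp$amplitude_uv), mean(ga$amplitude[sel]),
               tolerance = 1e-12)
})
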