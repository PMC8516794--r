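test_that("displacement is the per-sample Euclidean norm of the axes", {
  expect_equal(displacement(rbind(0, 0, 0))$d, 0)
  expect_equal(displacement(rbind(3, 4, 0))$d, 5)

  set.seed(12)
  g <- matrix(rnorm(300), 3)
  d <- displacement(g)$d
  oracle <- sapply(seq_len(ncol(g)), function(i) sqrt(sum(g[, i]^2)))
  expect_equal(d, oracle)

  # invariant to axis permutation and sign flips
  expect_equal(displacement(g[c(3, 1, 2), ])$d, d)
  expect_equal(displacement(-g)$d, d)

  expect_error(displacement(matrix(rnorm(8), 2)), "3 x samples")
})

test_that("the individual threshold is median + 4 IQR with type-7 quantiles", {
  expect_equal(individual_threshold(rep(2.5, 50))$threshold, 2.5)
  thr <- individual_threshold(1:100)
  expect_equal(thr$median_d, 50.5)
  expect_equal(thr$iqr_d, 49.5)
  expect_equal(thr$threshold, 50.5 + 4 * 49.5)
  expect_gte(thr$threshold, thr$median_d)

  # homogeneity under positive rescaling (deg/s vs rad/s immaterial)
  set.seed(13)
  x <- rexp(500)
  expect_equal(individual_threshold(3.7 * x)$threshold,
               3.7 * individual_threshold(x)$threshold)
  expect_error(individual_threshold(numeric(0)))
})

test_that("percent_below matches planted state mixtures and is monotone", {
  expect_equal(percent_below(rep(0, 100), 1), 1)

  # 30% ambulatory at 10x the still magnitude: ~70% below a mid threshold
  set.seed(14)
  n <- 20000
  amb <- seq_len(n) <= 0.3 * n
  sdv <- ifelse(amb, 10, 1)
  g <- rbind(rnorm(n, 0, sdv), rnorm(n, 0, sdv), rnorm(n, 0, sdv))
  d <- displacement(g)$d
  thr <- individual_threshold(d[!amb])   # still-only reference
  expect_equal(percent_below(d, thr), 0.70, tolerance = 0.02)

  thrs <- c(0.5, 1, 2, 5, 10)
  fr <- sapply(thrs, function(th) percent_below(d, th))
  expect_true(all(diff(fr) >= 0))
})

test_that("percentile profiles average participants and stay monotone", {
  set.seed(15)
  d1 <- tibble::tibble(participant = 1, block = 1, d = rexp(500))
  single <- percentile_profile(d1)
  expect_equal(single$profile$d,
               unname(quantile(d1$d, seq(0.01, 0.99, 0.01), type = 7)))
  expect_true(all(diff(single$profile$d) >= 0))

  # two participants with identical data: mean equals either
  d2 <- dplyr::bind_rows(d1, dplyr::mutate(d1, participant = 2))
  both <- percentile_profile(d2)
  expect_equal(both$profile$d, single$profile$d)

  thr <- tibble::tibble(participant = 1:2, threshold = c(2, 4))
  expect_equal(percentile_profile(d2, thr)$global_threshold, 3)
})

test_that("movement categories bin by rapid-block SDs and smooth out spikes", {
  rate <- 10
  n <- 600                                     # 60 s at 10 Hz
  base <- rep(1, n)
  stats_tbl <- tibble::tibble(participant = 1, mean_d = 1, sd_d = 0.5)

  flat <- tibble::tibble(participant = 1, t_s = (0:(n - 1)) / rate, d = base)
  tc <- categorize_timecourse(flat, stats_tbl, smooth_s = 10, rate_hz = rate)
  expect_true(all(tc$per_participant$category == 0))

  # one isolated spike vanishes under the 10-s moving median
  spiky <- flat; spiky$d[300] <- 100
  tc2 <- categorize_timecourse(spiky, stats_tbl, smooth_s = 10, rate_hz = rate)
  expect_true(all(tc2$per_participant$category == 0))

  # a sustained high bout peaks inside the bout
  bout <- flat; bout$d[200:400] <- 10
  tc3 <- categorize_timecourse(bout, stats_tbl, smooth_s = 10, rate_hz = rate)
  ga <- tc3$grand_average
  expect_equal(ga$t_s[which.max(ga$category)] %>% findInterval(c(20, 40)), 1)
  expect_equal(max(ga$category), 3)            # capped at 3 SDs

  expect_warning(
    categorize_timecourse(flat,
                          tibble::tibble(participant = 1, mean_d = 1, sd_d = 0),
                          smooth_s = 10, rate_hz = rate),
    "zero")
})
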