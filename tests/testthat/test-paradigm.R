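test_that("role sequences honour the run constraints exactly", {
  roles <- generate_sequence(160, 0.3, seed = 1)
  expect_length(roles, 160)
  expect_equal(sum(roles == "standard"), 112)
  expect_equal(sum(roles == "target"), 48)
  expect_equal(roles[1:4], rep("standard", 4))

  # brute-force scan for triple targets over many seeded draws
  for (s in 1:200) {
    r <- generate_sequence(160, 0.3, seed = s)
    runs <- rle(r)
    expect_false(any(runs$values == "target" & runs$lengths > 2))
    expect_equal(sum(r == "target"), 48)
  }
})

test_that("degenerate and infeasible sequences are handled", {
  expect_equal(generate_sequence(4, 0, seed = 1), rep("standard", 4))
  expect_error(generate_sequence(10, 0.9, seed = 1), "run of 3")
  expect_error(generate_sequence(3, 0.3))
})

test_that("rapid and sporadic ISIs follow the configured uniform ranges", {
  isis <- function(sch) {
    sc <- sch[sch$scored, ]
    diff(sc$onset_s) - sc$duration_s[1]
  }
  r_all <- unlist(lapply(1:50, function(s) isis(generate_schedule("rapid", seed = s))))
  expect_within(min(r_all), 0.5, 0.9)
  expect_within(max(r_all), 0.5, 0.9)
  # empirical mean within 3 SE of the midpoint
  se <- sqrt(0.4^2 / 12) / sqrt(length(r_all))
  expect_lt(abs(mean(r_all) - 0.7), 3 * se)

  s_isi <- isis(generate_schedule("sporadic", seed = 3))
  expect_within(min(s_isi), 56.2, 61.2)
  expect_within(max(s_isi), 56.2, 61.2)
})

test_that("rapid blocks run at ~9 targets per minute, mean period 2 s", {
  summ <- dplyr::bind_rows(lapply(1:100, function(s)
    schedule_summary(generate_schedule("rapid", seed = s))))
  expect_equal(mean(summ$duration_s / 160), 2.0, tolerance = 0.01)
  expect_equal(mean(summ$targets_per_min), 9, tolerance = 0.05)
})

test_that("sporadic blocks carry familiarization trials and a rest break", {
  sch <- generate_schedule("sporadic", seed = 7)
  fam <- sch[!sch$scored, ]
  expect_equal(nrow(fam), 20)
  expect_equal(nrow(sch[sch$scored, ]), 160)
  # alternating target/standard at each end
  expect_equal(fam$role[1:2], c("target", "standard"))
  expect_true(all(head(sch$trial[!sch$scored], 10) == 1:10))
  expect_equal(sum(sch$marker == "trial_rest_break_after"), 1)
  rest_pos <- which(sch$marker == "trial_rest_break_after")
  expect_equal(sum(sch$scored[1:rest_pos]), 80)
})

test_that("schedules round-trip through the TSV event table", {
  sch <- generate_schedule("sporadic", seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_schedule(sch, path)
  back <- read_schedule(path)
  expect_equal(as.data.frame(back), as.data.frame(sch), tolerance = 1e-12)
  expect_equal(attr(back, "variant"), "sporadic")
  expect_equal(attr(back, "isi_range_s"), c(56.2, 61.2))
})

test_that("double tones have the specified duration, equal RMS and spectral peak", {
  spec <- double_tone_spec()
  expect_equal(spec$total_ms, 1300)
  w_std <- render_double_tone(spec, "standard")
  w_tgt <- render_double_tone(spec, "target")
  expect_length(w_std, 1.3 * 44100)

  sounding <- function(w) {
    n1 <- round(0.7 * 44100); gap <- round(0.1 * 44100)
    c(w[1:n1], w[(n1 + gap + 1):length(w)])
  }
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(sounding(w_std)), rms(sounding(w_tgt)), tolerance = 1e-6)

  # periodogram peak of the first tone at the fundamental
  seg <- w_std[1:(0.7 * 44100)]
  p <- Mod(fft(seg))^2
  f <- (seq_along(p) - 1) * 44100 / length(p)
  keep <- f > 10 & f < 1000
  expect_equal(f[keep][which.max(p[keep])], 100, tolerance = 0.05)

  # silent gap really is silent
  expect_equal(max(abs(w_std[(0.7 * 44100 + 10):(0.8 * 44100 - 10)])), 0)
})
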