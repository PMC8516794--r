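# one fixed mixing matrix: calibration and test data share the source model
fixed_mix <- function(nch) {
  set.seed(1000 + nch)
  matrix(rnorm(nch^2), nch)
}

calib_data <- function(n_s = 60, nch = 6, rate = 250, seed = 1) {
  mix <- fixed_mix(nch)
  set.seed(seed)
  x <- mix %*% matrix(rnorm(nch * n_s * rate), nch)
  rownames(x) <- paste0("ch", seq_len(nch))
  x
}

test_that("calibration thresholds match the windowed-RMS statistics", {
  x <- calib_data()
  m <- asr_calibrate(x, 250, cutoff_k = 20, window_s = 0.5)
  # independent oracle: recompute component RMS stats with a plain loop
  xc <- x - rowMeans(x)
  y <- t(m$mixing) %*% xc
  w <- 125
  starts <- seq(1, ncol(y) - w + 1, by = 62)
  rms <- sapply(starts, function(s) sqrt(rowMeans(y[, s:(s + w - 1)]^2)))
  expect_equal(m$thresholds, rowMeans(rms) + 20 * apply(rms, 1, sd),
               tolerance = 1e-10)
  # thresholds ~ (1 + k * cv) * mean RMS
  cv <- apply(rms, 1, sd) / rowMeans(rms)
  expect_equal(m$thresholds, (1 + 20 * cv) * rowMeans(rms), tolerance = 1e-10)

  m5 <- asr_calibrate(x, 250, cutoff_k = 5)
  m40 <- asr_calibrate(x, 250, cutoff_k = 40)
  expect_true(all(m5$thresholds < m$thresholds))
  expect_true(all(m$thresholds < m40$thresholds))
})

test_that("duplicated channels make the calibration rank-deficient", {
  x <- calib_data(nch = 4)
  x[2, ] <- x[1, ]
  expect_error(asr_calibrate(x, 250), "rank-deficient")
  expect_error(asr_calibrate(calib_data(n_s = 10), 250), "30 s")
})

test_that("ASR is near-identity on clean data and exact at infinite cutoff", {
  x <- calib_data(seed = 2)
  m <- asr_calibrate(x, 250)
  rec <- new_recording(x, 250, rownames(x))
  out <- asr_apply(rec, m)
  rel <- sqrt(rowMeans((out$eeg - x)^2)) / apply(x, 1, stats::sd)
  expect_lt(max(rel), 0.05)

  m_inf <- m
  m_inf$thresholds <- rep(Inf, length(m$thresholds))
  expect_identical(asr_apply(rec, m_inf)$eeg, x)

  rec_bad <- new_recording(x[1:4, ], 250, rownames(x)[1:4])
  expect_error(asr_apply(rec_bad, m), "channel set")
})

test_that("planted bursts are suppressed by at least half", {
  x <- calib_data(seed = 3)
  m <- asr_calibrate(x, 250)
  set.seed(4)
  fresh <- calib_data(seed = 5)
  idx <- 4000:4200
  topo <- rnorm(6); topo <- topo / sqrt(mean(topo^2))
  bursty <- fresh
  bursty[, idx] <- bursty[, idx] +
    outer(topo * 20 * mean(apply(fresh, 1, stats::sd)), rnorm(length(idx)))
  rec <- new_recording(bursty, 250, rownames(x))
  out <- asr_apply(rec, m)
  rms_in <- sqrt(mean(bursty[, idx]^2))
  rms_out <- sqrt(mean(out$eeg[, idx]^2))
  expect_lt(rms_out, 0.5 * rms_in)
  # windows far from the burst stay put (no flagged component there)
  far <- 9000:11000
  expect_equal(out$eeg[, far], bursty[, far], tolerance = 1e-8)
})

test_that("spherical-spline interpolation reproduces constants and smooth fields", {
  labs <- ceegrid_labels()
  coords <- ceegrid_coords(labs)
  n <- 100

  const <- new_recording(matrix(2.5, length(labs), n), 250, labs)
  out <- interpolate_spherical(const, bad = "R6", coords)
  expect_equal(out$eeg[match("R6", labs), ], rep(2.5, n), tolerance = 1e-6)

  # leave-one-out on a smooth dipolar topography
  pos <- as.matrix(coords[match(labs, coords$label), c("x", "y", "z")])
  field <- pos %*% c(0.8, -0.5, 1.2)
  set.seed(6)
  src <- matrix(rnorm(n), 1)
  eeg <- field %*% src
  rec <- new_recording(eeg, 250, labs)
  held <- "R3"
  out <- interpolate_spherical(rec, bad = held, coords)
  i <- match(held, labs)
  expect_gt(stats::cor(out$eeg[i, ], eeg[i, ]), 0.9)

  # empty bad set is the identity
  expect_identical(interpolate_spherical(rec, character(0))$eeg, eeg)
  small <- new_recording(eeg[1:4, ], 250, labs[1:4])
  expect_error(interpolate_spherical(small, labs[2:4]), "4 good")
})
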