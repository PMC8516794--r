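# Small shared fixtures; everything is generated in code.

quiet_profile <- function(...) {
  participant_profile(noise_uv_rms = 0, rt_random_sds = c(0, 0),
                      miss_random_sds = c(0, 0), ...)
}

# four-channel montage: enough for the bipolar derivation, cheap to simulate
bipolar_config <- function(n_trials = 20, block_plan = "rapid",
                           calibration_s = 10, ...) {
  session_config(block_plan = block_plan, n_trials = n_trials,
                 channel_labels = c("R2", "R3", "R6", "R7"),
                 calibration_s = calibration_s, ...)
}

# epoch set built directly from a trials x channels x samples array
make_epoch_set <- function(data, roles, rate = 250, t0 = -0.2,
                           labels = paste0("ch", seq_len(dim(data)[2]))) {
  structure(
    list(data = data, t = t0 + (seq_len(dim(data)[3]) - 1) / rate,
         roles = roles, trial = seq_len(dim(data)[1]),
         kept = rep(TRUE, dim(data)[1]),
         reason = rep("none", dim(data)[1]),
         labels = labels, rate = rate, meta = list()),
    class = "epoch_set"
  )
}

expect_within <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
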