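# Shared fixtures, built in code.

# A short 6-trial session configuration for fast unit tests (2 M, 2 NM,
# 2 baseline); full-scale tests use the default 30-trial config.
tiny_config <- function(...) {
  cb_config(n_trials = 6L, m_trial_positions = c(2L, 5L),
            n_nm_trials = 2L, n_baseline_trials = 2L, ...)
}

# Deterministic raw recording: constant level with optional injected values.
flat_recording <- function(n = 1000, rate = 1000, level = 100) {
  pupil_recording(t = (seq_len(n) - 1) / rate, pupil = rep(level, n), rate = rate)
}

# Noise-free generator settings: a single unit impulse per detected M-trial
# at test onset, nothing else.
noise_free_params <- function(amp_delta = 1, offsets = 0) {
  pupil_gen_params(noise_sd = 0, drift_sd = 0, baseline_sd = 0,
                   amp_base = 0, amp_delta_detect = amp_delta,
                   amp_subject_gain_sd = 0,
                   blink_rate_hz = 0, saccade_rate_hz = 0,
                   response_offsets_s = offsets)
}

# Minimal M-trial covariate frame for behavior-only simulation.
m_trial_frame <- function(n_m = 8, confidence = 5, similarity = "similar") {
  data.frame(condition = "M", m_order = seq_len(n_m),
             confidence = confidence, similarity = similarity)
}

# Independent brute-force Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k_ok <- which(ps <= seq_len(m) * q / m)
  mask <- rep(FALSE, m)
  if (length(k_ok)) mask[o[seq_len(max(k_ok))]] <- TRUE
  mask
}
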