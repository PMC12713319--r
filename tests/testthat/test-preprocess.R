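# Preprocessing chain: interpolation, filtering, standardization,
# downsampling, IRF construction, nuisance regression, epoching and QC.

test_that("blink gaps are linearly interpolated and stay flagged invalid", {
  # flat neighbors: interior gap becomes the connecting line
  rec <- pupil_recording(t = (0:5) / 10, pupil = c(2, 2, 0, 0, 2, 2), rate = 10)
  out <- interpolate_blinks(rec, event_table(), pad_ms = 0)
  expect_equal(out$pupil, rep(2, 6))
  expect_identical(out$valid, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))

  # edge gap: constant extension of the first valid value
  rec <- pupil_recording(t = (0:4) / 10, pupil = c(0, 0, 3, 4, 5), rate = 10)
  out <- interpolate_blinks(rec, event_table(), pad_ms = 0)
  expect_equal(out$pupil, c(3, 3, 3, 4, 5))

  # a fully dead recording cannot be repaired
  rec <- pupil_recording(t = (0:3) / 10, pupil = rep(0, 4), rate = 10)
  expect_error(interpolate_blinks(rec, event_table()), "entirely invalid")
})

test_that("a 200 ms blink with 150 ms padding invalidates exactly 500 ms", {
  rec <- flat_recording(n = 2000, rate = 1000)
  rec$pupil[701:900] <- 0
  rec$valid[701:900] <- FALSE
  ev <- event_table("blink", 700, 900)
  out <- interpolate_blinks(rec, ev, pad_ms = 150)
  expect_equal(sum(!out$valid), 500)
  expect_identical(which(!out$valid), 551:1050)  # [550, 1050) ms
  expect_true(all(is.finite(out$pupil)))
})

test_that("band-pass filter removes DC, passes 1 Hz, blocks 20 Hz", {
  rate <- 100
  n <- 600 * rate
  t <- (seq_len(n) - 1) / rate
  mid <- seq(round(n * 0.25), round(n * 0.75))

  rec <- flat_recording(n = n, rate = rate, level = 57)
  rec <- interpolate_blinks(rec, event_table())
  out <- bandpass_filter(rec)
  expect_lt(max(abs(out$pupil[mid])), 1e-3)

  rec <- pupil_recording(t, sin(2 * pi * 1 * t) + 10, rate = rate)
  rec <- interpolate_blinks(rec, event_table())
  out <- bandpass_filter(rec)
  gain <- max(abs(out$pupil[mid]))
  expect_gte(gain, 0.9)
  expect_lte(gain, 1.0)

  rate <- 1000
  n <- 60 * rate
  t <- (seq_len(n) - 1) / rate
  rec <- pupil_recording(t, sin(2 * pi * 20 * t) + 10, rate = rate)
  rec <- interpolate_blinks(rec, event_table())
  out <- bandpass_filter(rec)
  mid <- seq(round(n * 0.25), round(n * 0.75))
  expect_lt(max(abs(out$pupil[mid])), 0.05)

  expect_error(bandpass_filter(rec, high = 600), "Nyquist")
})

test_that("standardization yields unit SD, is scale-invariant and idempotent", {
  coh <- generate_cohort(tiny_config(), n_subjects = 1, seed = 5)
  s <- coh$subjects[[1]]
  rec <- bandpass_filter(interpolate_blinks(s$recording, s$events))
  z <- standardize(rec)
  expect_equal(stats::sd(z$pupil[z$valid]), 1, tolerance = 1e-6)

  rec7 <- rec
  rec7$pupil <- rec$pupil * 7
  z7 <- standardize(rec7)
  expect_equal(z7$pupil, z$pupil, tolerance = 1e-9)
  expect_equal(z7$scale_au, 7 * z$scale_au, tolerance = 1e-9)

  expect_equal(standardize(z)$pupil, z$pupil, tolerance = 1e-9)

  flat <- interpolate_blinks(flat_recording(), event_table())
  flat$stage_tag <- "filtered"
  flat$pupil <- rep(0, length(flat$pupil))
  expect_error(standardize(flat), "zero variance")
})

test_that("downsampling decimates lengths, masks and preserves a 1 Hz tone", {
  coh <- generate_cohort(tiny_config(), n_subjects = 1, seed = 5)
  s <- coh$subjects[[1]]
  rec <- standardize(bandpass_filter(interpolate_blinks(s$recording, s$events)))
  n <- length(rec$pupil)
  out <- downsample(rec, 100)
  expect_length(out$pupil, ceiling(n / 10))
  expect_equal(out$rate, 100)

  # any invalid native sample in a block invalidates the decimated sample
  rec2 <- rec
  good_block <- which(vapply(seq(1, n - 10, by = 10),
                             function(i) all(rec$valid[i:(i + 9)]), TRUE))[1]
  i0 <- (good_block - 1) * 10 + 1
  rec2$valid[i0 + 3] <- FALSE
  out2 <- downsample(rec2, 100)
  expect_false(out2$valid[good_block])
  expect_true(out$valid[good_block])

  # amplitude of a 1 Hz tone survives 1000 -> 100 Hz decimation
  rate <- 1000
  t <- (seq_len(20 * rate) - 1) / rate
  tone <- pupil_recording(t, sin(2 * pi * t) + 2, rate = rate,
                          stage_tag = "standardized")
  dec <- downsample(tone, 100)
  expect_equal(max(dec$pupil) - 2, 1, tolerance = 0.01)

  expect_error(downsample(rec, 300), "integer multiple")
})

test_that("canonical IRF matches its closed form, peaks at t_max, starts at 0", {
  p <- irf_params(w = 10.1, t_max = 0.93)
  k <- pupil_irf(p, rate = 100)
  expect_equal(k[1], 0)
  expect_lte(abs((which.max(k) - 1) / 100 - 0.93), 0.01)
  # closed-form oracle at t = 0.5 * t_max
  t_half <- 0.5 * p$t_max
  expected <- (t_half^10.1 * exp(-10.1 * t_half / 0.93)) /
    (0.93^10.1 * exp(-10.1))
  expect_equal(expected, 0.5^10.1 * exp(5.05), tolerance = 1e-10)
  i <- round(t_half * 100) + 1
  grid_t <- (i - 1) / 100
  expect_equal(k[i], (grid_t^10.1 * exp(-10.1 * grid_t / 0.93)) /
                 (0.93^10.1 * exp(-10.1)), tolerance = 1e-12)
})

test_that("nuisance regression removes exact blink responses and passes through without events", {
  rate <- 100
  n <- 120 * rate
  k <- pupil_irf(irf_params(), rate)
  ev <- event_table("blink", c(10000, 40000, 80000), c(10200, 40150, 80300))
  x <- numeric(n)
  for (e in ev$end_ms) {
    i0 <- floor(e / 1000 * rate) + 1
    idx <- i0:(i0 + length(k) - 1)
    x[idx] <- x[idx] + 0.8 * k
  }
  rec <- pupil_recording((seq_len(n) - 1) / rate, x, rate = rate,
                         valid = rep(TRUE, n), stage_tag = "downsampled")
  out <- regress_nuisance(rec, ev)
  expect_lt(max(abs(out$pupil)), 1e-8)

  rec2 <- rec
  expect_warning(out2 <- regress_nuisance(rec2, event_table()), "pass-through")
  expect_equal(out2$pupil, rec$pupil)
})

test_that("nuisance regression halves the RMS error of a contaminated task trace", {
  set.seed(21)
  rate <- 100
  n <- 300 * rate
  k <- pupil_irf(irf_params(), rate)
  task <- numeric(n)
  for (on in seq(20, 280, by = 20) * rate) {
    idx <- on:(on + length(k) - 1)
    task[idx] <- task[idx] + k
  }
  bl_end <- sort(sample(seq(5000, 295000, by = 100), 40))
  ev <- event_table("blink", bl_end - 150, bl_end)
  contam <- task
  for (e in bl_end) {
    i0 <- floor(e / 1000 * rate) + 1
    idx <- i0:min(n, i0 + length(k) - 1)
    contam[idx] <- contam[idx] + 0.6 * k[seq_along(idx)]
  }
  contam <- contam + rnorm(n, 0, 0.02)
  rec <- pupil_recording((seq_len(n) - 1) / rate, contam, rate = rate,
                         valid = rep(TRUE, n), stage_tag = "downsampled")
  out <- regress_nuisance(rec, ev)
  rms_before <- sqrt(mean((contam - task)^2))
  rms_after <- sqrt(mean((out$pupil - (task - mean(task)))^2))
  expect_lt(rms_after, 0.5 * rms_before)
})

test_that("epoching has the documented grid, baseline rule and edge handling", {
  rate <- 100
  n <- 100 * rate
  rec <- pupil_recording((seq_len(n) - 1) / rate, rep(5, n), rate = rate,
                         valid = rep(TRUE, n), stage_tag = "nuisance_regressed")
  trials <- data.frame(trial_idx = 1:3, condition = c("M", "NM", "BASE"),
                       test_onset_s = c(10, 50, 99.5))
  ep <- epoch(rec, trials, window = c(-1, 5))
  expect_equal(dim(ep$data), c(3, 601))
  expect_equal(ep$time_s[101], 0)          # index of t = 0 is 100 (0-based)
  expect_equal(ep$data[1, ], rep(0, 601))  # constant trace, baseline-subtracted
  expect_false(ep$included[3])             # onset too close to the edge

  # epoch of a pure unit IRF at onset reproduces the kernel with 0 baseline
  k <- pupil_irf(irf_params(), rate)
  x <- numeric(n)
  x[30 * rate + 1:length(k)] <- k
  rec2 <- pupil_recording((seq_len(n) - 1) / rate, x, rate = rate,
                          valid = rep(TRUE, n), stage_tag = "nuisance_regressed")
  ep2 <- epoch(rec2, data.frame(trial_idx = 1, condition = "M", test_onset_s = 30))
  expect_equal(ep2$data[1, 101:501], k[1:401], tolerance = 1e-12)
  expect_equal(ep2$data[1, 1:100], rep(0, 100))
})

test_that("QC boundaries follow the more-than-a-third and 15-of-30 rules", {
  cfg <- cb_config()
  fake_epochs <- function(invalid_fraction) {
    structure(list(data = matrix(0, length(invalid_fraction), 601),
                   time_s = seq(-1, 5, by = 0.01),
                   trial_keys = data.frame(trial_idx = seq_along(invalid_fraction)),
                   invalid_fraction = invalid_fraction,
                   included = rep(TRUE, length(invalid_fraction)),
                   scale_au = 1), class = "cb_epochs")
  }
  # exactly 2000 ms invalid of 6000 ms: retained; 2001 ms: excluded
  q <- apply_qc(fake_epochs(c(2000 / 6000, 2001 / 6000)), cfg)
  expect_identical(q$epochs$included, c(TRUE, FALSE))

  q15 <- apply_qc(fake_epochs(rep(c(0.5, 0), c(15, 15))), cfg)
  expect_true(q15$subject_excluded)
  q14 <- apply_qc(fake_epochs(rep(c(0.5, 0), c(14, 16))), cfg)
  expect_false(q14$subject_excluded)
})

test_that("per-trial invalid fractions come from the native-rate mask", {
  coh <- generate_cohort(tiny_config(),
                         pupil = pupil_gen_params(blink_rate_hz = 0,
                                                  saccade_rate_hz = 0),
                         n_subjects = 1, seed = 8)
  s <- coh$subjects[[1]]
  on <- s$trials$test_onset_s[2]
  # inject a 900 ms dropout inside trial 2's window
  i0 <- round((on + 1) * 1000) + 1
  s$recording$pupil[i0:(i0 + 899)] <- 0
  s$recording$valid[i0:(i0 + 899)] <- FALSE
  prep <- suppressWarnings(preprocess_subject(s, coh$config))
  # 900 ms dropout + 150 ms padding on both sides = 1200 ms of 6000 ms
  expect_equal(prep$epochs$invalid_fraction[2], 1200 / 6000, tolerance = 1e-3)
  expect_true(prep$epochs$included[2])
})

test_that("pipeline stages refuse out-of-order input", {
  rec <- flat_recording()
  expect_error(bandpass_filter(rec), "stage")
  expect_error(standardize(rec), "stage")
  expect_error(downsample(rec), "stage")
  coh <- generate_cohort(tiny_config(), n_subjects = 1, seed = 1)
  s <- coh$subjects[[1]]
  rec <- interpolate_blinks(s$recording, s$events)
  expect_error(downsample(rec), "stage")
  expect_error(epoch(rec, s$trials), "stage")
})
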