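# Synthetic cohort generator. Emulates the statistical structure the
# downstream analyses assume: the 30-trial session (8 M-trials at fixed
# positions, 8 NM-trials at random positions, 14 baseline trials), subject
# reporting phenotypes, detection probability rising with trial order,
# confidence and pair dissimilarity, and continuous pupil traces with
# event-related dilation, blinks, saccades, drift and noise.

#' Behavioral generative parameters
#'
#' Detection of a manipulation on an M-trial is Bernoulli with
#' `logit p = b0 + b_trial*(order - 4.5) + b_conf*(conf - 5) + b_dissim*1[dissimilar]`,
#' where `order` is the M-trial index 1..8. Concurrent report happens only if
#' detected, with a probability set by the subject's reporting phenotype
#' (all-report / some-report / no-report). Retrospective report is Bernoulli
#' given detection, with a stimulus-memorability offset distinguishing the
#' color-photograph profile (`exp1`, high) from the monochrome-face profile
#' (`exp2`, low); independent false positives occur on non-manipulated pairs
#' in the memory task. The generator never produces a false concurrent or
#' retrospective report on a truly undetected M-trial.
#'
#' Phenotype weights default to the observed group sizes 8/41, 23/41, 10/41
#' (all / some / no report). The remaining defaults are free parameters
#' loosely calibrated so that pooled report rates and odds ratios land in the
#' plausible range; they are not estimates.
#'
#' @param phenotype_probs probabilities over `all_report`, `some_report`,
#'   `no_report`; must sum to 1.
#' @param b0,b_trial,b_conf,b_dissim detection-logit intercept and slopes
#'   (per M-order unit, per confidence unit, dissimilar-pair offset).
#' @param p_report_all,p_report_no concurrent-report probability given
#'   detection for the all-report / no-report phenotypes.
#' @param some_report_logit `c(a0, a1)`: some-report phenotype reports given
#'   detection with `logit p = a0 + a1*(order - 4.5)`.
#' @param possible_rate probability a detected, not concurrently reported
#'   M-trial yields a vague "possible detection" code.
#' @param retro_m0 retrospective-report logit intercept given detection.
#' @param retro_m_mem named memorability offsets per profile.
#' @param retro_fp_rate named per-pair false-positive rates in the memory
#'   task per profile.
#' @return An object of class `cb_behavior_params`.
#' @export
behavior_params <- function(phenotype_probs = c(all_report = 8 / 41,
                                                some_report = 23 / 41,
                                                no_report = 10 / 41),
                            b0 = 1.4, b_trial = 0.35, b_conf = 0.25,
                            b_dissim = 0.5,
                            p_report_all = 0.98, p_report_no = 0.02,
                            some_report_logit = c(a0 = -0.5, a1 = 0.3),
                            possible_rate = 0.02,
                            retro_m0 = 1.5,
                            retro_m_mem = c(exp1 = 1.0, exp2 = -1.5),
                            retro_fp_rate = c(exp1 = 0.033, exp2 = 0.087)) {
  p <- phenotype_probs
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8,
            all(c(p_report_all, p_report_no, possible_rate) >= 0),
            all(c(p_report_all, p_report_no, possible_rate) <= 1))
  structure(list(phenotype_probs = p, b0 = b0, b_trial = b_trial,
                 b_conf = b_conf, b_dissim = b_dissim,
                 p_report_all = p_report_all, p_report_no = p_report_no,
                 some_report_logit = some_report_logit,
                 possible_rate = possible_rate,
                 retro_m0 = retro_m0, retro_m_mem = retro_m_mem,
                 retro_fp_rate = retro_fp_rate),
            class = "cb_behavior_params")
}

#' Pupil-trace generative parameters
#'
#' The continuous trace is
#' `baseline + drift + sum(impulses * amp) (x) IRF + saccade transients + noise`,
#' in arbitrary device units, with blinks zeroing the pupil (plus 50 ms cosine
#' ramps) and flagged invalid. Every trial's test-image presentation injects
#' impulses of amplitude `amp_base`; detected M-trials add `amp_delta_detect`
#' and truly undetected M-trials add `amp_delta_undetect` (default 0, so any
#' covert-detection signature comes from detected-but-unreported trials).
#' `response_offsets_s` places the per-trial impulses relative to test-image
#' onset; the default train (one impulse per second of the 5 s presentation)
#' produces sustained dilation so the 2-4 s analysis window carries signal.
#'
#' @param baseline_mean,baseline_sd between-subject tonic pupil level, a.u.
#' @param drift_sd slow drift scale, a.u. per sqrt(s) (Wiener increments).
#' @param noise_sd white measurement noise, a.u.
#' @param amp_base,amp_delta_detect,amp_delta_undetect impulse amplitudes, a.u.
#' @param amp_subject_gain_sd SD of the per-subject multiplicative response
#'   gain (mean 1, floored at 0.2).
#' @param noise_subject_gain_sd SD of the per-subject multiplicative factor
#'   on `noise_sd` and `drift_sd` (mean 1, floored at 0.3). Together the two
#'   gains create between-subject heterogeneity in z-scored response size —
#'   the source of nonzero intraclass correlation in trial-level window
#'   models (a response gain alone mostly cancels under session-SD
#'   standardization).
#' @param irf an [irf_params()] object.
#' @param response_offsets_s impulse times relative to test onset, s.
#' @param blink_rate_hz Poisson blink rate.
#' @param blink_meanlog_ms,blink_sdlog_ms lognormal blink duration (ms scale);
#'   defaults give a ~120 ms median.
#' @param blink_response_amp amplitude of the IRF-shaped dilation transient
#'   time-locked to blink end, a.u. (what nuisance regression removes).
#' @param saccade_rate_hz Poisson saccade rate.
#' @param saccade_dur_ms nominal saccade duration.
#' @return An object of class `cb_pupil_params`.
#' @export
pupil_gen_params <- function(baseline_mean = 1000, baseline_sd = 100,
                             drift_sd = 5, noise_sd = 10,
                             amp_base = 20, amp_delta_detect = 15,
                             amp_delta_undetect = 0,
                             amp_subject_gain_sd = 0.25,
                             noise_subject_gain_sd = 0.3,
                             irf = irf_params(),
                             response_offsets_s = c(0, 1, 2, 3, 4),
                             blink_rate_hz = 0.25,
                             blink_meanlog_ms = log(120), blink_sdlog_ms = 0.4,
                             blink_response_amp = 5,
                             saccade_rate_hz = 1.5, saccade_dur_ms = 40) {
  stopifnot(baseline_sd >= 0, drift_sd >= 0, noise_sd >= 0,
            blink_rate_hz >= 0, saccade_rate_hz >= 0)
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 drift_sd = drift_sd, noise_sd = noise_sd,
                 amp_base = amp_base, amp_delta_detect = amp_delta_detect,
                 amp_delta_undetect = amp_delta_undetect,
                 amp_subject_gain_sd = amp_subject_gain_sd,
                 noise_subject_gain_sd = noise_subject_gain_sd, irf = irf,
                 response_offsets_s = response_offsets_s,
                 blink_rate_hz = blink_rate_hz,
                 blink_meanlog_ms = blink_meanlog_ms,
                 blink_sdlog_ms = blink_sdlog_ms,
                 blink_response_amp = blink_response_amp,
                 saccade_rate_hz = saccade_rate_hz,
                 saccade_dur_ms = saccade_dur_ms),
            class = "cb_pupil_params")
}

#' Build the deterministic trial schedule for one subject
#'
#' M-trials occupy the configured fixed positions; NM positions are drawn
#' uniformly without replacement from the remaining slots; the rest are
#' baseline trials. Phase durations are fixed, so test-image onsets are
#' deterministic given the condition sequence: each M/NM trial runs
#' pair -> ratings -> fixation -> test image -> report -> ITI, and each
#' baseline trial pair -> fixation -> test image -> ITI.
#'
#' @param config a [cb_config()].
#' @param lead_in_s quiet recording time before the first trial.
#' @param session_cap_s optional hard cap on session duration; exceeding it
#'   is an error.
#' @return data.frame with `trial_idx`, `condition`, `m_order` (1..8 for
#'   M-trials, `NA` otherwise), `start_s`, `test_onset_s`, `end_s`.
#' @export
build_schedule <- function(config, lead_in_s = 2, session_cap_s = NULL) {
  n <- config$n_trials
  condition <- rep("BASE", n)
  condition[config$m_trial_positions] <- "M"
  free <- setdiff(seq_len(n), config$m_trial_positions)
  nm_pos <- sort(sample(free, config$n_nm_trials))
  condition[nm_pos] <- "NM"
  pre <- ifelse(condition == "BASE",
                config$pair_presentation_s + config$fixation_s,
                config$pair_presentation_s + config$rating_s + config$fixation_s)
  dur <- pre + config$test_image_s + config$iti_s +
    ifelse(condition == "BASE", 0, config$report_s)
  start <- lead_in_s + c(0, cumsum(dur[-n]))
  if (!is.null(session_cap_s) && lead_in_s + sum(dur) > session_cap_s) {
    stop(sprintf("impossible schedule: %.1f s exceeds session cap %.1f s",
                 lead_in_s + sum(dur), session_cap_s))
  }
  out <- data.frame(trial_idx = seq_len(n), condition = condition,
                    m_order = NA_integer_, start_s = start,
                    test_onset_s = start + pre, end_s = start + dur)
  out$m_order[condition == "M"] <- seq_along(config$m_trial_positions)
  out
}

#' Simulate detection and reporting for one subject
#'
#' Applies the generative model of [behavior_params()] to a schedule:
#' detection is Bernoulli in the logistic model, concurrent report requires
#' detection and follows the phenotype, a detected-but-unreported trial may
#' be coded "possible", retrospective report is Bernoulli given detection,
#' and non-manipulated pairs receive independent memory-task false positives.
#' Consumes the current RNG stream.
#'
#' @param phenotype `"all_report"`, `"some_report"` or `"no_report"`.
#' @param params a [behavior_params()].
#' @param trials data.frame with columns `condition`, `m_order`,
#'   `confidence`, `similarity`.
#' @param profile `"exp1"` or `"exp2"` (memorability / false-positive rates).
#' @return `trials` with filled `concurrent_code`, `retrospective_flag`,
#'   `retro_false_positive_flag` plus ground-truth columns `detected`,
#'   `reported_concurrent`, `reported_retro`.
#' @export
generate_behavior <- function(phenotype, params, trials, profile = "exp1") {
  n <- nrow(trials)
  is_m <- trials$condition == "M"
  is_base <- trials$condition == "BASE"
  detected <- rep(FALSE, n)
  if (any(is_m)) {
    eta <- params$b0 +
      params$b_trial * (trials$m_order[is_m] - 4.5) +
      params$b_conf * (trials$confidence[is_m] - 5) +
      params$b_dissim * as.numeric(trials$similarity[is_m] == "dissimilar")
    detected[is_m] <- stats::runif(sum(is_m)) < stats::plogis(eta)
  }
  p_rep <- switch(phenotype,
    all_report = rep(params$p_report_all, sum(is_m)),
    no_report = rep(params$p_report_no, sum(is_m)),
    some_report = stats::plogis(params$some_report_logit[["a0"]] +
      params$some_report_logit[["a1"]] * (trials$m_order[is_m] - 4.5)),
    stop("unknown phenotype: ", phenotype))
  rep_conc <- rep(FALSE, n)
  rep_conc[is_m] <- detected[is_m] & (stats::runif(sum(is_m)) < p_rep)
  possible <- rep(FALSE, n)
  possible[is_m] <- detected[is_m] & !rep_conc[is_m] &
    (stats::runif(sum(is_m)) < params$possible_rate)
  p_retro <- stats::plogis(params$retro_m0 + params$retro_m_mem[[profile]])
  rep_retro <- rep(FALSE, n)
  rep_retro[is_m] <- detected[is_m] & (stats::runif(sum(is_m)) < p_retro)
  retro_fp <- rep(FALSE, n)
  retro_fp[!is_m] <- stats::runif(sum(!is_m)) < params$retro_fp_rate[[profile]]

  trials$concurrent_code <- ifelse(is_base, NA_character_,
    ifelse(rep_conc, "report", ifelse(possible, "possible", "none")))
  trials$retrospective_flag <- ifelse(is_base, NA, rep_retro)
  trials$retro_false_positive_flag <- ifelse(is_m, NA, retro_fp)
  trials$detected <- ifelse(is_m, detected, NA)
  trials$reported_concurrent <- ifelse(is_m, rep_conc, NA)
  trials$reported_retro <- ifelse(is_m, rep_retro, NA)
  trials
}

# Injected per-trial response amplitude given condition and detection truth.
.trial_amp <- function(condition, detected, pp) {
  amp <- rep(pp$amp_base, length(condition))
  is_m <- condition == "M"
  amp[is_m] <- amp[is_m] +
    ifelse(detected[is_m], pp$amp_delta_detect, pp$amp_delta_undetect)
  amp
}

#' Unit-amplitude response template on the epoch grid
#'
#' The noiseless per-trial response shape: the canonical IRF summed over the
#' configured impulse offsets, sampled on the epoch time grid at the target
#' rate. Multiplying by a trial's injected amplitude gives that trial's
#' expected event-related trace, which parameter-recovery tests compare
#' against pipeline output.
#'
#' @param config a [cb_config()].
#' @param pupil_params a [pupil_gen_params()].
#' @return Numeric vector on the epoch grid, with attribute `time_s`.
#' @export
response_template <- function(config, pupil_params = pupil_gen_params()) {
  rate <- config$target_rate_hz
  tt <- seq(config$epoch_window_s[1], config$epoch_window_s[2], by = 1 / rate)
  k <- pupil_irf(pupil_params$irf, rate)
  out <- numeric(length(tt))
  for (off in pupil_params$response_offsets_s) {
    i0 <- round((off - config$epoch_window_s[1]) * rate) + 1L
    idx <- i0:min(length(tt), i0 + length(k) - 1L)
    idx <- idx[idx >= 1]
    out[idx] <- out[idx] + k[seq_along(idx) + (idx[1] - i0)]
  }
  structure(out, time_s = tt)
}

# Simulate the continuous pupil trace + events for one subject.
.generate_pupil <- function(config, schedule, amp, pp) {
  rate <- config$sample_rate_hz
  dur <- max(schedule$end_s) + 2
  n <- round(dur * rate)
  t <- (seq_len(n) - 1) / rate

  baseline <- pp$baseline_mean + pp$baseline_sd * stats::rnorm(1)
  x <- rep(baseline, n)
  if (pp$drift_sd > 0) x <- x + cumsum(stats::rnorm(n, 0, pp$drift_sd / sqrt(rate)))

  k <- pupil_irf(pp$irf, rate)
  add_kernel <- function(x, i0, a) {
    if (a == 0) return(x)
    idx <- i0:min(n, i0 + length(k) - 1L)
    x[idx] <- x[idx] + a * k[seq_along(idx)]
    x
  }
  for (j in seq_len(nrow(schedule))) {
    for (off in pp$response_offsets_s) {
      i0 <- round((schedule$test_onset_s[j] + off) * rate) + 1L
      if (i0 <= n) x <- add_kernel(x, i0, amp[j])
    }
  }

  # saccades: biphasic transient (one sine cycle over 100 ms), amplitude
  # 0.1 * noise_sd, plus an event record
  n_sac <- stats::rpois(1, pp$saccade_rate_hz * dur)
  sac_start <- sort(stats::runif(n_sac, 0.5, dur - 0.5))
  trans <- 0.1 * pp$noise_sd * sin(2 * pi * seq(0, 0.1, by = 1 / rate) / 0.1)
  for (s in sac_start) {
    i0 <- round(s * rate) + 1L
    idx <- i0:min(n, i0 + length(trans) - 1L)
    x[idx] <- x[idx] + trans[seq_along(idx)]
  }

  if (pp$noise_sd > 0) x <- x + stats::rnorm(n, 0, pp$noise_sd)

  # blinks: zero the pupil across [start, end) with 50 ms cosine ramps, flag
  # invalid, and add an IRF-shaped recovery transient at blink end
  n_bl <- stats::rpois(1, pp$blink_rate_hz * dur)
  bl_start <- sort(stats::runif(n_bl, 1, dur - 1.5))
  bl_dur_ms <- stats::rlnorm(n_bl, pp$blink_meanlog_ms, pp$blink_sdlog_ms)
  valid <- rep(TRUE, n)
  if (n_bl > 0) {
    m <- .merge_intervals(round(bl_start * 1000), round(bl_start * 1000 + bl_dur_ms))
    bl_start_ms <- m$start; bl_end_ms <- m$end
    ramp_n <- round(0.05 * rate)
    # 1 -> ~0, strictly positive: an exact 0 would collide with the
    # missing-sample sentinel of the TSV dialect
    ramp <- (1 + cos(pi * seq_len(ramp_n) / (ramp_n + 1))) / 2
    for (b in seq_along(bl_start_ms)) {
      i1 <- floor(bl_start_ms[b] / 1000 * rate) + 1L
      i2 <- ceiling(bl_end_ms[b] / 1000 * rate)            # [start, end)
      i1c <- max(1L, i1); i2c <- min(n, i2)
      x[i1c:i2c] <- 0
      valid[i1c:i2c] <- FALSE
      pre <- (i1 - ramp_n):(i1 - 1L); pre <- pre[pre >= 1 & pre <= n]
      x[pre] <- x[pre] * rev(ramp)[seq_along(pre) + (ramp_n - length(pre))]
      post <- (i2 + 1L):(i2 + ramp_n); post <- post[post >= 1 & post <= n]
      x[post] <- x[post] * (1 - ramp[seq_along(post)])
      x <- add_kernel(x, min(i2 + 1L, n), pp$blink_response_amp)
    }
  } else {
    bl_start_ms <- bl_end_ms <- numeric(0)
  }

  if (n_sac > 0) {  # merge overlapping saccades up front (expected at 1.5 Hz)
    sm <- .merge_intervals(round(sac_start * 1000),
                           round(sac_start * 1000) + pp$saccade_dur_ms)
    sac_start_ms <- sm$start; sac_end_ms <- sm$end
  } else {
    sac_start_ms <- sac_end_ms <- numeric(0)
  }
  events <- event_table(
    kind = c(rep("blink", length(bl_start_ms)), rep("saccade", length(sac_start_ms))),
    start_ms = c(bl_start_ms, sac_start_ms),
    end_ms = c(bl_end_ms, sac_end_ms))

  list(recording = pupil_recording(t, x, rate = rate, valid = valid),
       events = events)
}

#' Generate a complete synthetic cohort
#'
#' For each subject: draws a reporting phenotype, builds the trial schedule,
#' assigns stimulus-pair covariates (similarity, confidence, esthetic
#' rating), simulates detection and reporting, and synthesizes the continuous
#' pupil recording with event-related dilation, drift, blinks, saccades and
#' noise. Deterministic for a fixed seed.
#'
#' @param config a [cb_config()]; its `profile` selects the Exp-1-like or
#'   Exp-2-like emulation.
#' @param behavior a [behavior_params()].
#' @param pupil a [pupil_gen_params()].
#' @param n_subjects number of subjects, `>= 1`.
#' @param seed integer RNG seed (mandatory).
#' @param session_cap_s optional session-duration cap passed to
#'   [build_schedule()].
#' @param force_detect `NA` (model-driven) or logical: force every M-trial's
#'   detection truth, for noise-free construction checks.
#' @return A list of class `cb_cohort`: `subjects` (named list, each with
#'   `recording`, `events`, `trials`), `ground_truth` (one row per trial:
#'   subject, phenotype, trial, condition, detection/report truth, injected
#'   amplitude), and `config`.
#' @export
generate_cohort <- function(config = cb_config(),
                            behavior = behavior_params(),
                            pupil = pupil_gen_params(),
                            n_subjects, seed,
                            session_cap_s = NULL, force_detect = NA) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  profile <- config$profile
  subjects <- list()
  gt <- list()
  for (s in seq_len(n_subjects)) {
    id <- sprintf("S%03d", s)
    phenotype <- sample(names(behavior$phenotype_probs), 1,
                        prob = behavior$phenotype_probs)
    sched <- build_schedule(config, session_cap_s = session_cap_s)
    n <- nrow(sched)
    is_base <- sched$condition == "BASE"
    sched$pair_id <- paste0("P", seq_len(n))
    sched$similarity <- ifelse(is_base, NA_character_,
                               sample(c("similar", "dissimilar"), n, replace = TRUE))
    conf <- pmin(9L, pmax(1L, round(stats::rnorm(n, 6, 1.8))))
    sched$confidence <- ifelse(is_base, NA_integer_, conf)
    sched$esthetic_rating <- ifelse(is_base, NA_integer_,
                                    sample(-4:4, n, replace = TRUE))
    beh <- generate_behavior(phenotype, behavior, sched, profile)
    if (!is.na(force_detect)) {
      is_m <- beh$condition == "M"
      beh$detected[is_m] <- force_detect
      if (!force_detect) beh$reported_concurrent[is_m] <- FALSE
    }
    gain <- max(0.2, 1 + stats::rnorm(1, 0, pupil$amp_subject_gain_sd))
    noise_gain <- max(0.3, 1 + stats::rnorm(1, 0, pupil$noise_subject_gain_sd))
    amp <- gain * .trial_amp(beh$condition, beh$detected, pupil)
    pupil_s <- pupil
    pupil_s$noise_sd <- pupil$noise_sd * noise_gain
    pupil_s$drift_sd <- pupil$drift_sd * noise_gain
    pup <- .generate_pupil(config, sched, amp, pupil_s)
    trials <- trial_table(beh[, c("trial_idx", "condition", "pair_id",
                                  "similarity", "confidence", "esthetic_rating",
                                  "test_onset_s", "concurrent_code",
                                  "retrospective_flag",
                                  "retro_false_positive_flag")], config)
    subjects[[id]] <- list(recording = pup$recording, events = pup$events,
                           trials = trials)
    gt[[id]] <- data.frame(subject = id, phenotype = phenotype,
                           trial_idx = beh$trial_idx, condition = beh$condition,
                           m_order = beh$m_order, detected = beh$detected,
                           reported_concurrent = beh$reported_concurrent,
                           reported_retro = beh$reported_retro,
                           amp = amp)
  }
  structure(list(subjects = subjects,
                 ground_truth = do.call(rbind, c(gt, list(make.row.names = FALSE))),
                 config = config),
            class = "cb_cohort")
}
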