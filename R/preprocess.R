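# Preprocessing chain, in fixed order:
#   interpolate -> filter -> standardize -> downsample -> regress_nuisance
#   -> epoch -> QC.
# Each stage stamps rec$stage_tag and refuses out-of-order input. The
# post-interpolation validity mask at the native rate is carried through as
# rec$native_valid so per-trial invalid fractions are computed at 1000 Hz
# regardless of later downsampling.

#' Interpolate blinks and missing data
#'
#' Samples inside each blink or missing-data interval, expanded by `pad_ms`
#' on both sides, are replaced by linear interpolation between the nearest
#' valid samples outside the padded interval; gaps touching the recording
#' edges are filled by constant extension of the nearest valid value. The
#' replaced and padded samples remain flagged invalid in the mask (they are
#' filled, not trusted).
#'
#' @param rec a raw `cb_recording`.
#' @param events a `cb_events` table (blink rows are used).
#' @param pad_ms symmetric padding around each interval, ms.
#' @return The recording at stage `"interpolated"`, with `native_valid`
#'   recording the mask at the native rate.
#' @export
interpolate_blinks <- function(rec, events, pad_ms = 150) {
  .require_stage(rec, "raw", "interpolate_blinks")
  bad <- !rec$valid | samples_in_events(rec, events, kind = "blink", pad_ms = pad_ms)
  # pad missing-sample runs symmetrically as well
  if (any(!rec$valid)) {
    r <- rle(!rec$valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    pad_n <- round(pad_ms / 1000 * rec$rate)
    for (i in which(r$values)) {
      lo <- max(1L, starts[i] - pad_n)
      hi <- min(length(bad), ends[i] + pad_n)
      bad[lo:hi] <- TRUE
    }
  }
  if (all(bad)) stop("recording entirely invalid; cannot interpolate")
  good <- which(!bad)
  x <- rec$pupil
  x[bad] <- stats::approx(good, rec$pupil[good], xout = which(bad), rule = 2)$y
  rec$pupil <- x
  rec$valid <- !bad
  rec$native_valid <- !bad
  rec$native_rate <- rec$rate
  rec$stage_tag <- "interpolated"
  rec
}

# Zero-phase third-order Butterworth band-pass, implemented as a cascade of
# third-order high-pass and low-pass sections: the single 6th-order
# band-pass transfer function is numerically unstable at a 1000 Hz rate with
# a 0.02 Hz corner, the cascade is not. signal::filtfilt starts from zero
# filter state, so the signal is demeaned first and padded by reflection for
# 60 s — several times the ~8 s time constant of the 0.02 Hz corner —
# leaving edge transients below 1e-3 of the DC step.
.filtfilt_pad <- function(flt, x, pad_n) {
  n <- length(x)
  pad_n <- min(pad_n, n - 1)
  xp <- c(2 * x[1] - x[(pad_n + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad_n)])
  y <- signal::filtfilt(flt, xp)
  y[(pad_n + 1):(pad_n + n)]
}

#' Band-pass filter a recording
#'
#' Applies a zero-phase (forward-backward) third-order Butterworth band-pass,
#' default 0.02-4 Hz, with demeaning and 60 s reflective padding at the
#' edges. Requires an interpolated (gap-free) recording.
#'
#' @param rec a `cb_recording` at stage `"interpolated"`.
#' @param low,high corner frequencies, Hz.
#' @param order filter order per section.
#' @return The recording at stage `"filtered"` (mean approximately zero).
#' @export
bandpass_filter <- function(rec, low = 0.02, high = 4.0, order = 3) {
  .require_stage(rec, "interpolated", "bandpass_filter")
  nyq <- rec$rate / 2
  if (high >= nyq || low >= nyq) stop("filter cutoff must lie below Nyquist")
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  pad_n <- round(60 * rec$rate)
  x <- rec$pupil - mean(rec$pupil)
  rec$pupil <- .filtfilt_pad(lp, .filtfilt_pad(hp, x, pad_n), pad_n)
  rec$stage_tag <- "filtered"
  rec
}

#' Standardize a recording to z-units
#'
#' Divides the (mean-free, filtered) signal by the standard deviation of its
#' valid samples; the per-trial pre-stimulus baseline subtraction that
#' completes the standardization contract happens in [epoch()]. The session
#' scale is stored as `rec$scale_au` so recovered effects can be mapped back
#' to acquisition units.
#'
#' @param rec a `cb_recording` at stage `"filtered"`.
#' @return The recording at stage `"standardized"`, unit SD over valid samples.
#' @export
standardize <- function(rec) {
  .require_stage(rec, c("filtered", "standardized"), "standardize")
  s <- stats::sd(rec$pupil[rec$valid])
  if (!is.finite(s) || s == 0) stop("zero variance; cannot standardize")
  rec$pupil <- rec$pupil / s
  rec$scale_au <- (rec$scale_au %||% 1) * s
  rec$stage_tag <- "standardized"
  rec
}

#' Downsample a recording by decimation
#'
#' Keeps every `rate/target`-th sample (the 4 Hz low-pass already provides
#' anti-aliasing). A decimated sample is valid only if every native sample in
#' its block was valid.
#'
#' @param rec a `cb_recording` at stage `"standardized"`.
#' @param target target rate, Hz; must divide the native rate.
#' @return The recording at stage `"downsampled"`, length `ceiling(n/ratio)`.
#' @export
downsample <- function(rec, target = 100) {
  .require_stage(rec, "standardized", "downsample")
  ratio <- rec$rate / target
  if (ratio != round(ratio)) stop("native rate must be an integer multiple of target")
  ratio <- as.integer(ratio)
  n <- length(rec$pupil)
  idx <- seq.int(1L, n, by = ratio)
  block_valid <- vapply(idx, function(i) {
    all(rec$valid[i:min(n, i + ratio - 1L)])
  }, logical(1))
  rec$t <- rec$t[idx]
  rec$pupil <- rec$pupil[idx]
  rec$valid <- block_valid
  if (!is.null(rec$gaze_x)) rec$gaze_x <- rec$gaze_x[idx]
  if (!is.null(rec$gaze_y)) rec$gaze_y <- rec$gaze_y[idx]
  rec$rate <- target
  rec$stage_tag <- "downsampled"
  rec
}

#' Regress blink and saccade responses out of the pupil signal
#'
#' Builds one regressor per event kind — a unit-impulse train at event end
#' times (recovery onsets) convolved with the canonical pupil kernel — plus
#' an intercept, fits ordinary least squares over the valid samples, and
#' returns the residual (the intercept term is retained as zero since the
#' filtered signal is mean-free). With no events the recording passes through
#' unchanged, with a warning.
#'
#' @param rec a `cb_recording` at stage `"downsampled"`.
#' @param events a `cb_events` table.
#' @param irf an [irf_params()] object.
#' @return The recording at stage `"nuisance_regressed"`.
#' @export
regress_nuisance <- function(rec, events, irf = irf_params()) {
  .require_stage(rec, "downsampled", "regress_nuisance")
  n <- length(rec$pupil)
  k <- pupil_irf(irf, rec$rate)
  regressor <- function(kind) {
    ev <- events[events$kind == kind, , drop = FALSE]
    if (!nrow(ev)) return(NULL)
    r <- numeric(n)
    for (e in ev$end_ms) {
      i0 <- floor(e / 1000 * rec$rate) + 1L
      if (i0 > n) next
      idx <- i0:min(n, i0 + length(k) - 1L)
      r[idx] <- r[idx] + k[seq_along(idx)]
    }
    if (all(r == 0)) NULL else r
  }
  cols <- Filter(Negate(is.null),
                 list(blink = regressor("blink"), saccade = regressor("saccade")))
  if (!length(cols)) {
    warning("no blink/saccade events; nuisance regression is a pass-through")
    rec$stage_tag <- "nuisance_regressed"
    return(rec)
  }
  X <- cbind(intercept = 1, do.call(cbind, cols))
  fit <- stats::lm.fit(X[rec$valid, , drop = FALSE], rec$pupil[rec$valid])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  rec$pupil <- rec$pupil - as.vector(X %*% beta)
  rec$stage_tag <- "nuisance_regressed"
  rec
}

#' Extract per-trial epochs
#'
#' Cuts a window (default -1..5 s) around each trial's test-image onset from
#' the fully preprocessed recording and subtracts the trial's pre-stimulus
#' baseline (mean over [-1, 0) s). The per-trial invalid fraction is computed
#' from the native-rate mask over the half-open window
#' `[onset + w1, onset + w2)`. Trials whose window exceeds the recording are
#' marked not included.
#'
#' @param rec a `cb_recording` at stage `"nuisance_regressed"`.
#' @param trials a `cb_trials` table (or any data.frame with `trial_idx`,
#'   `condition`, `test_onset_s`).
#' @param window epoch window in seconds relative to test onset.
#' @return An object of class `cb_epochs`: `data` (trials x timepoints, one
#'   row per trial, z-units, baseline-subtracted), `time_s`, `trial_keys`,
#'   `invalid_fraction`, `included`, `scale_au`.
#' @export
epoch <- function(rec, trials, window = c(-1, 5)) {
  .require_stage(rec, "nuisance_regressed", "epoch")
  rate <- rec$rate
  n <- length(rec$pupil)
  n_t <- round((window[2] - window[1]) * rate) + 1L
  time_s <- window[1] + (seq_len(n_t) - 1L) / rate
  bl <- which(time_s >= window[1] & time_s < 0)
  nat_rate <- rec$native_rate %||% rate
  nat_valid <- rec$native_valid %||% rec$valid
  nat_n <- round((window[2] - window[1]) * nat_rate)

  data <- matrix(NA_real_, nrow(trials), n_t)
  invalid_fraction <- rep(NA_real_, nrow(trials))
  included <- rep(TRUE, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    onset <- trials$test_onset_s[i]
    i0 <- round((onset + window[1] - rec$t[1]) * rate) + 1L
    if (i0 < 1 || i0 + n_t - 1L > n) {
      included[i] <- FALSE
      next
    }
    seg <- rec$pupil[i0:(i0 + n_t - 1L)]
    data[i, ] <- seg - mean(seg[bl])
    j0 <- round((onset + window[1]) * nat_rate) + 1L
    jdx <- j0:(j0 + nat_n - 1L)
    jdx <- jdx[jdx >= 1 & jdx <= length(nat_valid)]
    invalid_fraction[i] <- if (length(jdx)) mean(!nat_valid[jdx]) else NA_real_
  }
  structure(list(data = data, time_s = time_s,
                 trial_keys = as.data.frame(trials),
                 invalid_fraction = invalid_fraction,
                 included = included,
                 scale_au = rec$scale_au %||% 1),
            class = "cb_epochs")
}

#' Apply trial- and subject-level quality control
#'
#' A trial is excluded iff strictly more than `max_invalid_fraction` (default
#' 1/3, i.e. more than 2 s of the 6 s window) of its native-rate samples are
#' invalid; exactly at the boundary is retained. The subject is excluded iff
#' the number of excluded trials reaches `subject_exclude_at` (default 15 of
#' 30).
#'
#' @param epochs a `cb_epochs` object.
#' @param config a [cb_config()] (thresholds).
#' @return A list: `epochs` (with `included` updated), `subject_excluded`,
#'   `n_excluded`, `n_trials`.
#' @export
apply_qc <- function(epochs, config = cb_config()) {
  bad <- !epochs$included |
    (!is.na(epochs$invalid_fraction) &
       epochs$invalid_fraction > config$max_invalid_fraction)
  epochs$included <- !bad
  n_excl <- sum(bad)
  list(epochs = epochs,
       subject_excluded = n_excl >= config$subject_exclude_at,
       n_excluded = n_excl,
       n_trials = length(bad))
}

#' Run the full preprocessing chain for one subject
#'
#' Convenience wrapper applying, in order: blink interpolation, band-pass
#' filtering, standardization, downsampling, nuisance regression, epoching
#' and QC, with all thresholds taken from the configuration.
#'
#' @param subject list with `recording`, `events`, `trials` (one element of a
#'   cohort).
#' @param config a [cb_config()].
#' @param irf an [irf_params()] for the nuisance regressors.
#' @return A list: `epochs` (QC-applied `cb_epochs`), `qc` (subject verdict),
#'   `recording` (final stage).
#' @export
preprocess_subject <- function(subject, config = cb_config(), irf = irf_params()) {
  rec <- interpolate_blinks(subject$recording, subject$events,
                            pad_ms = config$blink_pad_ms)
  rec <- bandpass_filter(rec, config$filter_band_hz[1], config$filter_band_hz[2],
                         config$filter_order)
  rec <- standardize(rec)
  rec <- downsample(rec, config$target_rate_hz)
  rec <- suppressWarnings(regress_nuisance(rec, subject$events, irf))
  ep <- epoch(rec, subject$trials, window = config$epoch_window_s)
  qc <- apply_qc(ep, config)
  list(epochs = qc$epochs,
       qc = qc[c("subject_excluded", "n_excluded", "n_trials")],
       recording = rec)
}

#' Preprocess every subject of a cohort
#'
#' @param cohort a `cb_cohort` (or the result of [read_cohort()]).
#' @param config configuration; defaults to the cohort's own.
#' @param drop_excluded drop subjects failing the QC verdict.
#' @return Named list of per-subject [preprocess_subject()] results.
#' @export
preprocess_cohort <- function(cohort, config = cohort$config, drop_excluded = TRUE) {
  out <- lapply(cohort$subjects, preprocess_subject, config = config)
  if (drop_excluded) {
    out <- Filter(function(s) !s$qc$subject_excluded, out)
  }
  out
}
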