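#' Continuous pupil recording
#'
#' Container for one session of uniformly sampled pupil (and optionally gaze)
#' data. Time is seconds since session start; the validity mask marks samples
#' that are missing or blink-contaminated. The `stage_tag` records the last
#' preprocessing step applied, and each pipeline stage refuses out-of-order
#' input based on it.
#'
#' @param t numeric, seconds; strictly increasing with constant step `1/rate`.
#' @param pupil numeric, arbitrary units (raw) or z-units (standardized).
#' @param rate sampling rate in Hz.
#' @param valid logical validity mask (default: finite, non-zero pupil).
#' @param gaze_x,gaze_y optional gaze position, screen degrees.
#' @param stage_tag provenance label (default `"raw"`).
#' @return An object of class `cb_recording`.
#' @export
pupil_recording <- function(t, pupil, rate, valid = NULL,
                            gaze_x = NULL, gaze_y = NULL, stage_tag = "raw") {
  n <- length(t)
  if (length(pupil) != n) stop("t and pupil must have equal length")
  if (n >= 2) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("non-monotone time")
    if (max(abs(dt - 1 / rate)) > 1e-6) stop("sampling step must be constant 1/rate")
  }
  if (is.null(valid)) valid <- is.finite(pupil) & pupil != 0
  stopifnot(length(valid) == n)
  structure(list(t = as.numeric(t), pupil = as.numeric(pupil), rate = rate,
                 valid = as.logical(valid), gaze_x = gaze_x, gaze_y = gaze_y,
                 stage_tag = stage_tag),
            class = "cb_recording")
}

#' @export
print.cb_recording <- function(x, ...) {
  cat(sprintf("<cb_recording> %d samples @ %g Hz (%.1f s), %.1f%% valid, stage '%s'\n",
              length(x$t), x$rate, length(x$t) / x$rate,
              100 * mean(x$valid), x$stage_tag))
  invisible(x)
}

.require_stage <- function(rec, allowed, op) {
  if (!rec$stage_tag %in% allowed) {
    stop(sprintf("%s() expects a recording at stage %s, got '%s' (pipeline order is fixed)",
                 op, paste(sQuote(allowed), collapse = "/"), rec$stage_tag))
  }
  invisible(rec)
}

#' Blink / saccade event table
#'
#' Intervals use the half-open convention `[start_ms, end_ms)`: a sample at
#' time `t` seconds lies inside an event iff `start_ms <= 1000*t < end_ms`.
#' Overlapping or touching intervals of the same kind are merged (with a
#' warning when a genuine overlap was present).
#'
#' @param kind character, `"blink"` or `"saccade"`.
#' @param start_ms,end_ms integer milliseconds, `end_ms > start_ms`.
#' @return A `data.frame` of class `cb_events` with columns
#'   `kind`, `start_ms`, `end_ms`, sorted by kind then start.
#' @export
event_table <- function(kind = character(), start_ms = numeric(), end_ms = numeric()) {
  if (length(kind) == 1 && length(start_ms) > 1) kind <- rep(kind, length(start_ms))
  stopifnot(length(kind) == length(start_ms), length(kind) == length(end_ms))
  if (length(kind) && !all(kind %in% c("blink", "saccade"))) {
    stop("event kind must be 'blink' or 'saccade'")
  }
  if (any(end_ms <= start_ms)) stop("event end_ms must exceed start_ms")
  out <- do.call(rbind, lapply(unique(kind), function(k) {
    i <- which(kind == k)
    merged <- .merge_intervals(start_ms[i], end_ms[i])
    if (merged$overlapped) {
      warning(sprintf("overlapping %s events merged", k), call. = FALSE)
    }
    data.frame(kind = k, start_ms = merged$start, end_ms = merged$end)
  }))
  if (is.null(out)) out <- data.frame(kind = character(),
                                      start_ms = numeric(), end_ms = numeric())
  out <- out[order(out$kind, out$start_ms), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cb_events", "data.frame")
  out
}

.merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- me <- numeric(0)
  overlapped <- FALSE
  for (i in seq_along(start)) {
    if (length(ms) && start[i] <= me[length(me)]) {
      if (start[i] < me[length(me)]) overlapped <- TRUE
      me[length(me)] <- max(me[length(me)], end[i])
    } else {
      ms <- c(ms, start[i]); me <- c(me, end[i])
    }
  }
  list(start = ms, end = me, overlapped = overlapped)
}

#' Which samples fall inside events of a given kind
#'
#' @param rec a `cb_recording`.
#' @param events a `cb_events` table.
#' @param kind event kind to use, or `NULL` for all.
#' @param pad_ms symmetric padding applied to each interval, ms.
#' @return logical vector over samples, `TRUE` inside a (padded) event.
#' @export
samples_in_events <- function(rec, events, kind = NULL, pad_ms = 0) {
  ev <- if (is.null(kind)) events else events[events$kind == kind, , drop = FALSE]
  inside <- rep(FALSE, length(rec$t))
  t_ms <- rec$t * 1000
  for (i in seq_len(nrow(ev))) {
    inside <- inside | (t_ms >= ev$start_ms[i] - pad_ms & t_ms < ev$end_ms[i] + pad_ms)
  }
  inside
}

#' Trial table
#'
#' One row per trial of a session. Rating, report and similarity fields are
#' only defined for M/NM trials; baseline trials have no report phase and
#' carry `NA` there.
#'
#' @param df data.frame with columns `trial_idx`, `condition` (`"M"`, `"NM"`,
#'   `"BASE"`), `pair_id`, `similarity` (`"similar"`/`"dissimilar"`/`NA`),
#'   `confidence` (1..9), `esthetic_rating` (-4..4), `test_onset_s`,
#'   `concurrent_code` (`"report"`/`"possible"`/`"none"`/`NA`),
#'   `retrospective_flag`, `retro_false_positive_flag`.
#' @param config a `cb_config`; condition counts are checked against it.
#' @return The validated data.frame, classed `cb_trials`.
#' @export
trial_table <- function(df, config) {
  req <- c("trial_idx", "condition", "pair_id", "similarity", "confidence",
           "esthetic_rating", "test_onset_s", "concurrent_code",
           "retrospective_flag", "retro_false_positive_flag")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("trial table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$condition %in% c("M", "NM", "BASE"))) stop("unknown trial condition")
  counts <- table(factor(df$condition, levels = c("M", "NM", "BASE")))
  expected <- c(M = length(config$m_trial_positions),
                NM = config$n_nm_trials, BASE = config$n_baseline_trials)
  if (!all(counts == expected)) {
    stop(sprintf("condition counts (M=%d, NM=%d, BASE=%d) do not match config (M=%d, NM=%d, BASE=%d)",
                 counts["M"], counts["NM"], counts["BASE"],
                 expected["M"], expected["NM"], expected["BASE"]))
  }
  mn <- df$condition != "BASE"
  if (any(!is.na(df$confidence[mn]) & (df$confidence[mn] < 1 | df$confidence[mn] > 9))) {
    stop("confidence must lie in 1..9")
  }
  if (any(!is.na(df$esthetic_rating[mn]) &
          (df$esthetic_rating[mn] < -4 | df$esthetic_rating[mn] > 4))) {
    stop("esthetic_rating must lie in -4..4")
  }
  df <- df[order(df$trial_idx), , drop = FALSE]
  if (any(diff(df$test_onset_s) <= 0)) stop("test_onset_s must increase with trial_idx")
  if (any(!is.na(df$concurrent_code[df$condition == "BASE"]))) {
    stop("baseline trials carry no report codes")
  }
  rownames(df) <- NULL
  class(df) <- c("cb_trials", "data.frame")
  df
}
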