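#' Experiment configuration
#'
#' Builds the configuration object shared by every pipeline stage: the
#' 30-trial session schedule (8 manipulated trials at fixed positions, 8
#' non-manipulated trials at random positions, 14 baseline trials), the trial
#' timeline, acquisition and analysis rates, the filter band, the epoch and
#' analysis windows, and the QC and FDR thresholds.
#'
#' Two named profiles are provided. `"exp1"` shows each stimulus pair for 3 s
#' (color photographs); `"exp2"` shows it for 5 s (monochrome faces). All
#' other defaults are shared.
#'
#' @param profile `"exp1"` or `"exp2"`; selects the pair-presentation duration.
#' @param ... named overrides for any configuration field.
#'
#' @return An object of class `cb_config`: a validated named list with fields
#'   `n_trials`, `m_trial_positions`, `n_nm_trials`, `n_baseline_trials`,
#'   `pair_presentation_s`, `rating_s`, `fixation_s`, `test_image_s`,
#'   `report_s`, `iti_s`, `sample_rate_hz`, `target_rate_hz`,
#'   `epoch_window_s`, `analysis_window_s`, `filter_band_hz`, `filter_order`,
#'   `blink_pad_ms`, `fdr_q`, `max_invalid_fraction`, `subject_exclude_at`,
#'   `profile`.
#' @examples
#' cfg <- cb_config()
#' cfg$m_trial_positions
#' @export
cb_config <- function(profile = c("exp1", "exp2"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    n_trials            = 30L,
    m_trial_positions   = c(7L, 10L, 14L, 16L, 20L, 22L, 26L, 29L),
    n_nm_trials         = 8L,
    n_baseline_trials   = 14L,
    pair_presentation_s = if (profile == "exp1") 3.0 else 5.0,
    rating_s            = 4.0,   # fixed nominal duration of the rating phase
    fixation_s          = 2.5,
    test_image_s        = 5.0,
    report_s            = 4.0,   # fixed nominal duration of the report window
    iti_s               = 2.0,
    sample_rate_hz      = 1000,
    target_rate_hz      = 100,
    epoch_window_s      = c(-1.0, 5.0),
    analysis_window_s   = c(2.0, 4.0),
    filter_band_hz      = c(0.02, 4.0),
    filter_order        = 3L,
    blink_pad_ms        = 150,
    fdr_q               = 0.05,
    max_invalid_fraction = 1 / 3,
    subject_exclude_at  = 15L,
    profile             = profile
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
}

#' Validate an experiment configuration
#'
#' Checks the structural invariants: manipulated-trial positions strictly
#' increasing and inside the session, condition counts summing to the trial
#' count, the analysis window inside the epoch window, and a filter band
#' below Nyquist.
#'
#' @param cfg a configuration list.
#' @return `cfg`, classed `cb_config`, invisibly unchanged otherwise.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  pos <- cfg$m_trial_positions
  if (any(diff(pos) <= 0)) stop("m_trial_positions must be strictly increasing")
  if (any(pos < 1L) || any(pos > cfg$n_trials)) {
    stop("m_trial_positions must lie in 1..n_trials")
  }
  if (length(pos) + cfg$n_nm_trials + cfg$n_baseline_trials != cfg$n_trials) {
    stop("condition counts must sum to n_trials")
  }
  ew <- cfg$epoch_window_s; aw <- cfg$analysis_window_s
  if (!(ew[1] < ew[2]) || !(aw[1] < aw[2])) stop("windows must be increasing")
  if (aw[1] < ew[1] || aw[2] > ew[2]) {
    stop("analysis window must lie inside the epoch window")
  }
  band <- cfg$filter_band_hz
  if (!(0 < band[1] && band[1] < band[2] && band[2] < cfg$sample_rate_hz / 2)) {
    stop("filter band must satisfy 0 < low < high < Nyquist")
  }
  if (cfg$sample_rate_hz %% cfg$target_rate_hz != 0) {
    stop("sample_rate_hz must be an integer multiple of target_rate_hz")
  }
  structure(cfg, class = "cb_config")
}

#' Read / write a configuration as YAML
#'
#' @param path file path of the YAML sidecar.
#' @return `read_config()` returns a validated `cb_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- cb_config(profile = cfg$profile %||% "exp1")
  base[names(cfg)] <- cfg
  validate_config(base)
}

#' @rdname read_config
#' @param cfg a `cb_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
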