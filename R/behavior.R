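# Report-category derivation and behavioral summaries: tabulations with the
# printed-rounding convention, inclusion-exclusion unions, signal detection
# scores for the retrospective memory task, and inter-rater kappa.

#' Derive the report category of M-trials
#'
#' Mapping from coded labels to the analysis category:
#' \itemize{
#'   \item `report` -> `CR` (concurrent report);
#'   \item `none` + retrospective -> `RR` (retrospective-only report);
#'   \item `none` + no retrospective -> `NR` (no report);
#'   \item `possible` + no retrospective -> `EXCLUDED` (vague report,
#'     dropped from analysis);
#'   \item `possible` + retrospective -> `CR` (the trial demonstrably
#'     detected; flagged via the `possible_cr` attribute).
#' }
#'
#' @param concurrent_code character vector in `report`/`possible`/`none`.
#' @param retrospective_flag logical vector.
#' @return factor with levels `CR`, `RR`, `NR`, `EXCLUDED`; attribute
#'   `possible_cr` marks the `possible`-but-retro trials counted as CR.
#' @export
derive_category <- function(concurrent_code, retrospective_flag) {
  stopifnot(length(concurrent_code) == length(retrospective_flag))
  known <- concurrent_code %in% c("report", "possible", "none")
  if (any(!known)) stop("unknown concurrent_code: ",
                        paste(unique(concurrent_code[!known]), collapse = ", "))
  out <- ifelse(concurrent_code == "report", "CR",
         ifelse(concurrent_code == "possible" & retrospective_flag, "CR",
         ifelse(concurrent_code == "possible", "EXCLUDED",
         ifelse(retrospective_flag, "RR", "NR"))))
  structure(factor(out, levels = c("CR", "RR", "NR", "EXCLUDED")),
            possible_cr = concurrent_code == "possible" & retrospective_flag)
}

#' Round a percentage half-up at a fixed number of decimals
#'
#' `round()` in R rounds half to even; printed results use half-up.
#'
#' @param x numeric.
#' @param decimals digits after the decimal point.
#' @return rounded numeric.
#' @export
pct_round <- function(x, decimals = 1) {
  f <- 10^decimals
  floor(x * f + 0.5) / f
}

#' Percentage of a count, with printed rounding
#'
#' @param count,total nonnegative counts; a zero denominator yields `NA`.
#' @param decimals digits after the decimal point.
#' @return percentage in 0..100, rounded half-up.
#' @export
report_pct <- function(count, total, decimals = 1) {
  out <- pct_round(100 * count / total, decimals)
  out[rep_len(total == 0, length(out))] <- NA_real_
  out
}

#' Union of concurrent and retrospective report counts
#'
#' Inclusion-exclusion: `union = concurrent + retrospective - both`.
#'
#' @param n_concurrent,n_retro,n_both,total counts.
#' @param decimals rounding of the percentage.
#' @return list with `count` and `pct`.
#' @export
report_union <- function(n_concurrent, n_retro, n_both, total, decimals = 1) {
  u <- n_concurrent + n_retro - n_both
  list(count = u, pct = report_pct(u, total, decimals))
}

#' Tabulate report categories
#'
#' Counts and percentages of report categories over the M-trials of one or
#' more trial tables, overall and (when the grouping columns are present)
#' per M-trial position and per subject.
#'
#' @param trials a trial table or a list of them; needs `condition`,
#'   `concurrent_code`, `retrospective_flag`, optionally `subject` and
#'   `m_order`.
#' @param decimals rounding of percentages.
#' @return list with `overall` (per-category counts, pct with the EXCLUDED
#'   cell removed from the denominator of analysis shares), `by_position`
#'   (category x M-order counts, if `m_order` present), `by_subject`
#'   (category x subject counts, if `subject` present), and `n_m_trials`.
#' @export
tabulate_reports <- function(trials, decimals = 1) {
  if (!is.data.frame(trials)) {
    trials <- do.call(rbind, lapply(names(trials), function(id) {
      df <- as.data.frame(trials[[id]])
      df$subject <- df$subject %||% id
      df
    }))
  }
  m <- trials[trials$condition == "M", , drop = FALSE]
  if (is.null(m$m_order)) {  # M-trial index 1..8 within each session
    grp <- if (is.null(m$subject)) rep(1, nrow(m)) else m$subject
    m$m_order <- stats::ave(m$trial_idx, grp, FUN = rank)
  }
  cat <- derive_category(m$concurrent_code, m$retrospective_flag)
  counts <- table(cat)
  n_total <- nrow(m)
  n_analyzed <- n_total - counts[["EXCLUDED"]]
  overall <- data.frame(category = names(counts),
                        count = as.integer(counts),
                        pct_of_m = report_pct(as.integer(counts), n_total, decimals),
                        pct_of_analyzed = report_pct(as.integer(counts),
                                                     n_analyzed, decimals))
  out <- list(overall = overall, n_m_trials = n_total, n_analyzed = n_analyzed)
  if (!is.null(m$m_order)) {
    out$by_position <- table(category = cat, m_order = m$m_order)
  }
  if (!is.null(m$subject)) {
    out$by_subject <- table(category = cat, subject = m$subject)
  }
  out
}

#' Signal-detection score from response counts
#'
#' `H = hits/(hits+misses)`, `F = fa/(fa+cr)`,
#' `d' = qnorm(H) - qnorm(F)`. With `correction = "loglinear"`, 0.5 is added
#' to every cell before computing the rates whenever any raw rate is 0 or 1;
#' with `correction = "none"`, an extreme rate is an error (infinite d').
#'
#' @param n_hits,n_misses,n_fa,n_cr nonnegative counts; signal trials
#'   (`hits+misses`) and noise trials (`fa+cr`) must be positive.
#' @param correction `"none"` or `"loglinear"`.
#' @return list of class `cb_sdt`: `hit_rate`, `fa_rate`, `d_prime`,
#'   `correction_applied`.
#' @export
sdt_score <- function(n_hits, n_misses, n_fa, n_cr,
                      correction = c("none", "loglinear")) {
  correction <- match.arg(correction)
  stopifnot(n_hits >= 0, n_misses >= 0, n_fa >= 0, n_cr >= 0,
            n_hits + n_misses > 0, n_fa + n_cr > 0)
  H <- n_hits / (n_hits + n_misses)
  F <- n_fa / (n_fa + n_cr)
  applied <- "none"
  if (any(c(H, F) %in% c(0, 1))) {
    if (correction == "none") {
      stop("hit or false-alarm rate of 0/1 gives infinite d'; use the loglinear correction")
    }
    H <- (n_hits + 0.5) / (n_hits + n_misses + 1)
    F <- (n_fa + 0.5) / (n_fa + n_cr + 1)
    applied <- "loglinear"
  }
  structure(list(hit_rate = H, fa_rate = F,
                 d_prime = stats::qnorm(H) - stats::qnorm(F),
                 correction_applied = applied),
            class = "cb_sdt")
}

#' Per-subject retrospective-memory SDT scores for a cohort
#'
#' For each subject: hits = retrospectively reported M-trials, misses = the
#' remaining M-trials, false alarms = false-positive responses on
#' non-manipulated pairs, correct rejections = the remaining lure pairs. The
#' lure denominator defaults to the number of non-M pairs on the memory
#' sheet (22 of 30 under the default design). Reports the per-subject mean
#' d' (the primary convention) and the pooled-count d' (secondary).
#'
#' @param trials_by_subject named list of trial tables.
#' @param n_lures lure-pair count per subject.
#' @param correction passed to [sdt_score()] (per-subject extreme rates are
#'   common, so the loglinear correction is the default here).
#' @return list: `per_subject` data.frame (subject, H, F, d_prime),
#'   `mean_d_prime`, `pooled` (`cb_sdt` on summed counts).
#' @export
sdt_cohort <- function(trials_by_subject, n_lures = 22,
                       correction = "loglinear") {
  rows <- lapply(names(trials_by_subject), function(id) {
    tr <- as.data.frame(trials_by_subject[[id]])
    m <- tr$condition == "M"
    hits <- sum(tr$retrospective_flag[m], na.rm = TRUE)
    misses <- sum(m) - hits
    fa <- sum(tr$retro_false_positive_flag[!m], na.rm = TRUE)
    s <- sdt_score(hits, misses, fa, n_lures - fa, correction = correction)
    data.frame(subject = id, n_hits = hits, n_misses = misses, n_fa = fa,
               hit_rate = s$hit_rate, fa_rate = s$fa_rate, d_prime = s$d_prime)
  })
  per_subject <- do.call(rbind, rows)
  pooled <- sdt_score(sum(per_subject$n_hits), sum(per_subject$n_misses),
                      sum(per_subject$n_fa),
                      length(rows) * n_lures - sum(per_subject$n_fa),
                      correction = correction)
  list(per_subject = per_subject,
       mean_d_prime = mean(per_subject$d_prime),
       pooled = pooled)
}

#' Cohen's kappa for two raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with the expected agreement `p_e` from
#' the product of marginal label distributions.
#'
#' @param labels_a,labels_b equal-length categorical vectors.
#' @return list of class `cb_kappa`: `kappa` (NA with `undefined = TRUE`
#'   when both raters are constant and identical), `percent_agreement`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) > 0)
  lv <- union(unique(labels_a), unique(labels_b))
  a <- factor(labels_a, levels = lv)
  b <- factor(labels_b, levels = lv)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < .Machine$double.eps) {
    return(structure(list(kappa = NA_real_, percent_agreement = 100 * p_o,
                          undefined = TRUE), class = "cb_kappa"))
  }
  structure(list(kappa = (p_o - p_e) / (1 - p_e),
                 percent_agreement = 100 * p_o, undefined = FALSE),
            class = "cb_kappa")
}
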