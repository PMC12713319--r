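# Leave-one-subject-out midpoint-threshold classification of trial-level
# window pupil responses, with exact binomial testing against the majority
# class proportion.

#' Exact binomial test against the majority class proportion
#'
#' One-sided upper tail: `P(X >= n_correct | n_total, p0)`.
#'
#' @param n_correct,n_total counts, `0 <= n_correct <= n_total`.
#' @param p0 chance proportion in `(0, 1)`.
#' @return p-value.
#' @export
binomial_vs_majority <- function(n_correct, n_total, p0) {
  stopifnot(n_correct >= 0, n_correct <= n_total, p0 > 0, p0 < 1)
  stats::pbinom(n_correct - 1, n_total, p0, lower.tail = FALSE)
}

#' Leave-one-subject-out midpoint-threshold classifier
#'
#' For each held-out subject, the decision threshold is the midpoint of the
#' mean window responses of the two classes computed from all other
#' subjects' trials; the held-out subject's trials are predicted as the
#' higher class when their value exceeds the threshold (ties go to the
#' reference class, conservative toward chance). Accuracy is pooled over all
#' held-out trials and tested against the majority class proportion with an
#' exact binomial test.
#'
#' Training class means default to pooling all other subjects' trials
#' (trial-weighted); `fold_means = "subject"` averages per-subject means
#' instead.
#'
#' @param values numeric trial-level window responses.
#' @param labels two-level factor/character (e.g. `M`/`NM` or `CR`/`NCR`).
#' @param subjects subject id per trial.
#' @param positive the label predicted for values above threshold; default
#'   the first of `sort(unique(labels))` alphabetically later — set
#'   explicitly for clarity. The other level is the reference (tie) class.
#' @param fold_means `"pooled"` or `"subject"`.
#' @return object of class `cb_loso`: `predicted`, `correct`, `n_correct`,
#'   `n_total`, `accuracy`, `p0`, `p_value`, `thresholds` (per fold),
#'   `skipped_subjects`.
#' @export
loso_classify <- function(values, labels, subjects, positive = NULL,
                          fold_means = c("pooled", "subject")) {
  fold_means <- match.arg(fold_means)
  stopifnot(length(values) == length(labels),
            length(values) == length(subjects))
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("exactly two classes required")
  if (is.null(positive)) positive <- lv[1]
  negative <- setdiff(lv, positive)
  ids <- unique(subjects)
  if (length(ids) < 2) stop("at least 2 subjects required")

  class_mean <- function(sel, lab) {
    v <- values[sel & labels == lab]
    if (fold_means == "pooled") mean(v)
    else mean(tapply(v, subjects[sel & labels == lab], mean))
  }
  predicted <- rep(NA_character_, length(values))
  thresholds <- stats::setNames(rep(NA_real_, length(ids)), ids)
  skipped <- character(0)
  for (id in ids) {
    train <- subjects != id
    if (!all(lv %in% labels[train])) {
      warning("fold for subject ", id, " is missing a class; skipped")
      skipped <- c(skipped, id)
      next
    }
    thr <- (class_mean(train, positive) + class_mean(train, negative)) / 2
    thresholds[id] <- thr
    test <- subjects == id
    predicted[test] <- ifelse(values[test] > thr, positive, negative)
  }
  scored <- !is.na(predicted)
  correct <- predicted[scored] == labels[scored]
  n_correct <- sum(correct)
  n_total <- sum(scored)
  p0 <- max(table(labels[scored])) / n_total
  p_value <- if (p0 > 0 && p0 < 1) binomial_vs_majority(n_correct, n_total, p0)
             else NA_real_  # degenerate: scored trials all one class
  structure(list(predicted = predicted, correct = correct,
                 n_correct = n_correct, n_total = n_total,
                 accuracy = n_correct / n_total, p0 = p0,
                 p_value = p_value,
                 thresholds = thresholds, skipped_subjects = skipped),
            class = "cb_loso")
}

#' @export
print.cb_loso <- function(x, ...) {
  cat(sprintf("<cb_loso> %d/%d correct (%.1f%%), majority %.1f%%, binomial p = %.3g\n",
              x$n_correct, x$n_total, 100 * x$accuracy, 100 * x$p0, x$p_value))
  invisible(x)
}
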