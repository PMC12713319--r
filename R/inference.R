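# Time-series and window statistics over preprocessed epochs, FDR control,
# and mixed models of reporting behavior and pupil size.

#' Benjamini-Hochberg rejection mask
#'
#' Step-up rule: reject all p-values at or below `p_(k*)`, where
#' `k* = max{k : p_(k) <= k q / m}`.
#'
#' @param p p-values in `[0, 1]`.
#' @param q FDR level.
#' @return logical rejection mask, same length as `p`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  if (!length(p)) return(logical(0))
  stats::p.adjust(p, method = "BH") <= q
}

# Paired t on per-subject values; one-sided "greater" means mean(x - y) > 0.
.paired_t <- function(x, y, sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  d <- x - y
  n <- sum(is.finite(d))
  if (n < 2) return(list(t = NA_real_, p = NA_real_, n = n, estimable = FALSE))
  d <- d[is.finite(d)]
  se <- stats::sd(d) / sqrt(n)
  tt <- if (se == 0 && mean(d) == 0) 0 else mean(d) / se
  p <- if (sided == "greater") stats::pt(tt, n - 1, lower.tail = FALSE)
       else 2 * stats::pt(-abs(tt), n - 1)
  list(t = tt, p = p, n = n, estimable = TRUE)
}

#' Subject-level mean epoch traces per condition group
#'
#' Averages each subject's included trials within each group, producing one
#' subjects x timepoints matrix per group. Default groups: the three trial
#' conditions plus the post-hoc M-trial report categories (CR, NCR = M
#' without concurrent report, RR, NR; EXCLUDED trials are dropped from every
#' M group).
#'
#' @param prep named list of [preprocess_subject()] results.
#' @param groups named list of predicate functions over `trial_keys` rows.
#' @return list with `traces` (named list of matrices, rownames = subject
#'   ids; a subject with no included trial in a group carries `NA`) and
#'   `time_s`.
#' @export
condition_traces <- function(prep, groups = default_groups()) {
  ids <- names(prep)
  time_s <- prep[[1]]$epochs$time_s
  traces <- lapply(groups, function(g) {
    m <- do.call(rbind, lapply(ids, function(id) {
      ep <- prep[[id]]$epochs
      sel <- ep$included & g(ep$trial_keys)
      if (!any(sel)) rep(NA_real_, length(time_s))
      else colMeans(ep$data[sel, , drop = FALSE])
    }))
    rownames(m) <- ids
    m
  })
  list(traces = traces, time_s = time_s)
}

#' Default condition groups
#'
#' @return named list of predicates over trial-table rows: `M`, `NM`, `BASE`,
#'   `CR`, `NCR`, `RR`, `NR`.
#' @export
default_groups <- function() {
  cat_of <- function(tk) {
    out <- rep(NA_character_, nrow(tk))
    m <- tk$condition == "M"
    out[m] <- as.character(derive_category(tk$concurrent_code[m],
                                           tk$retrospective_flag[m]))
    out
  }
  list(
    M    = function(tk) tk$condition == "M" & cat_of(tk) != "EXCLUDED",
    NM   = function(tk) tk$condition == "NM",
    BASE = function(tk) tk$condition == "BASE",
    CR   = function(tk) !is.na(cat_of(tk)) & cat_of(tk) == "CR",
    NCR  = function(tk) !is.na(cat_of(tk)) & cat_of(tk) %in% c("RR", "NR"),
    RR   = function(tk) !is.na(cat_of(tk)) & cat_of(tk) == "RR",
    NR   = function(tk) !is.na(cat_of(tk)) & cat_of(tk) == "NR"
  )
}

#' Pointwise paired t-tests along the epoch
#'
#' Per time point on the test grid (default 0..5 s), a paired t-test on
#' subject-level mean traces, with Benjamini-Hochberg correction across the
#' grid (one family per contrast) and an uncorrected alpha = 0.05 mask for
#' exploratory reporting when nothing survives FDR. Pairing is by subject
#' id, not row position.
#'
#' @param trace_a,trace_b subjects x time matrices with subject-id rownames.
#' @param time_s epoch time grid matching the columns.
#' @param sided `"greater"` (a > b, directional) or `"two.sided"`.
#' @param q FDR level.
#' @param test_window portion of the epoch tested, seconds.
#' @return object of class `cb_pointwise`: `time_s`, `t_stat`, `p`,
#'   `fdr_mask`, `uncorrected_mask`, `sided`, `n`.
#' @export
pointwise_paired_tests <- function(trace_a, trace_b, time_s,
                                   sided = c("greater", "two.sided"),
                                   q = 0.05, test_window = c(0, 5)) {
  sided <- match.arg(sided)
  ids <- intersect(rownames(trace_a), rownames(trace_b))
  a <- trace_a[ids, , drop = FALSE]
  b <- trace_b[ids, , drop = FALSE]
  ok <- stats::complete.cases(a) & stats::complete.cases(b)
  if (sum(ok) < 2) {
    warning("fewer than 2 paired subjects; contrast skipped")
    return(NULL)
  }
  d <- a[ok, , drop = FALSE] - b[ok, , drop = FALSE]
  keep <- time_s >= test_window[1] & time_s <= test_window[2]
  d <- d[, keep, drop = FALSE]
  n <- nrow(d)
  mu <- colMeans(d)
  se <- apply(d, 2, stats::sd) / sqrt(n)
  tt <- mu / se
  tt[se == 0 & mu == 0] <- 0   # degenerate: identical conditions
  p <- if (sided == "greater") stats::pt(tt, n - 1, lower.tail = FALSE)
       else 2 * stats::pt(-abs(tt), n - 1)
  structure(list(time_s = time_s[keep], t_stat = tt, p = p,
                 fdr_mask = fdr_bh(p, q), uncorrected_mask = p <= 0.05,
                 sided = sided, n = n),
            class = "cb_pointwise")
}

#' Trial-level analysis-window means
#'
#' Mean epoch value over the analysis window (default 2-4 s) for every
#' included trial of every subject, in z-units, with report category
#' attached.
#'
#' @param prep named list of [preprocess_subject()] results.
#' @param window analysis window, seconds.
#' @return data.frame: `subject`, `trial_idx`, `condition`, `category`,
#'   `m_order`, `confidence`, `similarity`, `value`.
#' @export
window_trial_means <- function(prep, window = c(2, 4)) {
  out <- lapply(names(prep), function(id) {
    ep <- prep[[id]]$epochs
    keep <- which(ep$included)
    if (!length(keep)) return(NULL)
    cols <- ep$time_s >= window[1] & ep$time_s <= window[2]
    tk <- ep$trial_keys[keep, , drop = FALSE]
    cat <- rep(NA_character_, nrow(tk))
    m <- tk$condition == "M"
    if (any(m)) cat[m] <- as.character(derive_category(tk$concurrent_code[m],
                                                       tk$retrospective_flag[m]))
    mo <- match(tk$trial_idx[m], sort(tk$trial_idx[m]))
    m_order <- rep(NA_integer_, nrow(tk)); m_order[m] <- mo
    data.frame(subject = id, trial_idx = tk$trial_idx,
               condition = tk$condition, category = cat, m_order = m_order,
               confidence = tk$confidence, similarity = tk$similarity,
               value = rowMeans(ep$data[keep, cols, drop = FALSE]))
  })
  do.call(rbind, out)
}

#' Subject-level window statistics, baseline-normalized
#'
#' Per subject and group, the mean window value and its baseline-normalized
#' counterpart (group mean minus the subject's baseline-trial mean over the
#' same window; the baseline group is 0 by construction). Subtraction, not a
#' ratio, so conditions below baseline keep their sign.
#'
#' @param trial_means result of [window_trial_means()].
#' @return data.frame: `subject`, `group`, `mean`, `normalized`, `n_trials`.
#' @export
window_stats <- function(trial_means) {
  groups <- list(
    M    = quote(condition == "M" & (is.na(category) | category != "EXCLUDED")),
    NM   = quote(condition == "NM"),
    BASE = quote(condition == "BASE"),
    CR   = quote(!is.na(category) & category == "CR"),
    NCR  = quote(!is.na(category) & category %in% c("RR", "NR")),
    RR   = quote(!is.na(category) & category == "RR"),
    NR   = quote(!is.na(category) & category == "NR")
  )
  out <- lapply(split(trial_means, trial_means$subject), function(df) {
    base_mean <- mean(df$value[df$condition == "BASE"])
    rows <- lapply(names(groups), function(g) {
      sel <- eval(groups[[g]], df)
      n <- sum(sel)
      m <- if (n) mean(df$value[sel]) else NA_real_
      data.frame(subject = df$subject[1], group = g, mean = m,
                 normalized = m - base_mean, n_trials = n)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Window-analysis test battery
#'
#' For each M-trial group (M, CR, NCR, RR, NR): against baseline one-sided
#' (group > baseline, i.e. normalized mean > 0), against NM-trials one-sided
#' (group > NM), and every pair of groups two-sided — the directional tests
#' reflect the expectation that detection dilates the pupil. Comparisons
#' with fewer than 2 paired subjects are reported as not estimable.
#'
#' @param stats_df result of [window_stats()].
#' @return data.frame: `contrast`, `t`, `p`, `n`, `estimable`, `sided`.
#' @export
window_tests <- function(stats_df) {
  wide <- function(g) {
    d <- stats_df[stats_df$group == g & stats_df$n_trials > 0, ]
    stats::setNames(d$mean, d$subject)
  }
  m_groups <- c("M", "CR", "NCR", "RR", "NR")
  rows <- list()
  add <- function(name, x, y, sided) {
    ids <- intersect(names(x), names(y))
    r <- .paired_t(x[ids], y[ids], sided)
    rows[[length(rows) + 1]] <<- data.frame(contrast = name, t = r$t, p = r$p,
                                            n = r$n, estimable = r$estimable,
                                            sided = sided)
  }
  base <- wide("BASE"); nm <- wide("NM")
  for (g in m_groups) {
    v <- wide(g)
    add(paste0(g, " > BASE"), v, base, "greater")
    add(paste0(g, " > NM"), v, nm, "greater")
  }
  add("NM > BASE", nm, base, "greater")
  for (i in seq_along(m_groups)) for (j in seq_len(i - 1)) {
    add(paste(m_groups[j], "vs", m_groups[i]),
        wide(m_groups[j]), wide(m_groups[i]), "two.sided")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mixed-effects logistic regression of reporting
#'
#' Models concurrent or retrospective report of M-trials with trial order
#' (M-trial index 1..8), confidence and pair similarity as fixed effects and
#' a participant random intercept, by maximum likelihood (Laplace). Trials
#' coded EXCLUDED are dropped. Odds ratios with Wald 95% CIs; a constant
#' outcome is flagged as separation and not fit.
#'
#' @param trials data.frame of M-trials across subjects with columns
#'   `subject`, `m_order`, `confidence`, `similarity`, `concurrent_code`,
#'   `retrospective_flag`.
#' @param outcome `"concurrent"` or `"retrospective"`.
#' @param extra_fixed optional character vector of extra fixed-effect columns.
#' @return object of class `cb_glmm`: `coef` data.frame (term, beta, or,
#'   ci_lo, ci_hi, p), `sigma2_subject`, `converged`, `separation`, `fit`.
#' @export
fit_report_glmm <- function(trials, outcome = c("concurrent", "retrospective"),
                            extra_fixed = character()) {
  outcome <- match.arg(outcome)
  df <- if ("condition" %in% names(trials)) {
    trials[trials$condition == "M", , drop = FALSE]
  } else trials
  cat <- derive_category(df$concurrent_code, df$retrospective_flag)
  df <- df[cat != "EXCLUDED", , drop = FALSE]
  df$y <- if (outcome == "concurrent") df$concurrent_code == "report"
          else df$retrospective_flag
  df$similar <- as.numeric(df$similarity == "similar")
  if (length(unique(df$y)) < 2) {
    return(structure(list(coef = NULL, sigma2_subject = NA_real_,
                          converged = FALSE, separation = TRUE, fit = NULL),
                     class = "cb_glmm"))
  }
  rhs <- paste(c("m_order", "confidence", "similar", extra_fixed), collapse = " + ")
  fml <- stats::as.formula(paste("y ~", rhs, "+ (1 | subject)"))
  fit <- lme4::glmer(fml, data = df, family = stats::binomial(),
                     control = lme4::glmerControl(calc.derivs = FALSE))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- beta / se
  coef <- data.frame(term = names(beta), beta = beta,
                     or = exp(beta),
                     ci_lo = exp(beta - 1.96 * se),
                     ci_hi = exp(beta + 1.96 * se),
                     p = 2 * stats::pnorm(-abs(z)))
  rownames(coef) <- NULL
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(coef = coef,
                 sigma2_subject = as.numeric(lme4::VarCorr(fit)$subject),
                 converged = is.null(msgs) || !length(msgs),
                 separation = any(abs(beta) > 15), fit = fit),
            class = "cb_glmm")
}

#' Linear mixed model of trial-level window pupil size
#'
#' Fits `value ~ <fixed> + (1 | subject)` on trial-level window means (the
#' standard model family: trial type; report category; trial order and
#' confidence). REML by default. Wald 95% CIs and normal-approximation
#' p-values; variance components and the intraclass correlation are
#' reported, with a singularity flag.
#'
#' @param df trial-level data with `subject`, `value` and the fixed-effect
#'   columns.
#' @param fixed right-hand-side formula string, e.g. `"condition"`.
#' @param reml logical; REML (default) or ML.
#' @return object of class `cb_lmm`: `coef` (term, beta, ci_lo, ci_hi, p),
#'   `sigma2_subject`, `sigma2_resid`, `icc`, `singular`, `fit`.
#' @export
fit_pupil_lmm <- function(df, fixed, reml = TRUE) {
  fml <- stats::as.formula(paste("value ~", fixed, "+ (1 | subject)"))
  fit <- lme4::lmer(fml, data = df, REML = reml)
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- beta / se
  coef <- data.frame(term = names(beta), beta = beta,
                     ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
                     p = 2 * stats::pnorm(-abs(z)))
  rownames(coef) <- NULL
  s2s <- as.numeric(lme4::VarCorr(fit)$subject)
  s2e <- stats::sigma(fit)^2
  structure(list(coef = coef, sigma2_subject = s2s, sigma2_resid = s2e,
                 icc = icc(s2s, s2e), singular = lme4::isSingular(fit),
                 fit = fit),
            class = "cb_lmm")
}

#' Intraclass correlation from variance components
#'
#' Share of total variance attributable to between-subject differences:
#' `sigma2_subject / (sigma2_subject + sigma2_residual)`.
#'
#' @param sigma2_subject,sigma2_residual nonnegative variance components.
#' @return value in `[0, 1]`; `NA` (undefined) when both are zero.
#' @export
icc <- function(sigma2_subject, sigma2_residual) {
  stopifnot(sigma2_subject >= 0, sigma2_residual >= 0)
  tot <- sigma2_subject + sigma2_residual
  if (tot == 0) return(NA_real_)
  sigma2_subject / tot
}
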