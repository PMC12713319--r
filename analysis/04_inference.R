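#!/usr/bin/env Rscript
# Time-series and window statistics, mixed models.
#
# Pointwise one-sided paired t-tests (M > NM, M > baseline, CR > NM,
# NCR > NM) on 0..5 s with BH-FDR across the 501 time points of each
# contrast; 2-4 s window means normalized to baseline trials with the full
# paired test battery; mixed-effects logistic regressions of concurrent and
# retrospective report; linear mixed models of trial-level window pupil
# size with ICC.

suppressMessages(library(pupilcb))

prep <- readRDS("scratch/prep_exp1.rds")
cohort <- readRDS("scratch/cohort_exp1.rds")

tr <- condition_traces(prep)
contrasts <- list(c("M", "NM"), c("M", "BASE"), c("CR", "NM"), c("NCR", "NM"))
pw_rows <- list()
for (ct in contrasts) {
  r <- pointwise_paired_tests(tr$traces[[ct[1]]], tr$traces[[ct[2]]],
                              tr$time_s, sided = "greater")
  if (is.null(r)) next
  pw_rows[[paste(ct, collapse = ">")]] <-
    data.frame(contrast = paste(ct[1], ">", ct[2]), time_s = r$time_s,
               t = r$t_stat, p = r$p, fdr = r$fdr_mask, unc = r$uncorrected_mask)
  n_fdr <- sum(r$fdr_mask)
  message(sprintf("%s > %s: %d/%d time points survive FDR (n = %d subjects)%s",
                  ct[1], ct[2], n_fdr, length(r$p), r$n,
                  if (n_fdr == 0) sprintf(" [%d uncorrected]", sum(r$uncorrected_mask)) else ""))
}
write.table(do.call(rbind, pw_rows), "results/pointwise_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tm <- window_trial_means(prep)
ws <- window_stats(tm)
wt <- window_tests(ws)
write.table(ws, "results/window_stats.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(wt, "results/window_tests.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message("window test battery:")
print(wt, digits = 3)

trials_all <- do.call(rbind, lapply(names(cohort$subjects), function(id) {
  df <- as.data.frame(cohort$subjects[[id]]$trials)
  df$subject <- id
  m <- df$condition == "M"
  df$m_order <- NA_integer_
  df$m_order[m] <- rank(df$trial_idx[m])
  df
}))
for (oc in c("concurrent", "retrospective")) {
  fit <- fit_report_glmm(trials_all, oc)
  if (!is.null(fit$coef)) {
    message(sprintf("report GLMM (%s): OR_trial %.2f [%.2f, %.2f], OR_conf %.2f, sigma2_subj %.2f%s",
                    oc, fit$coef$or[2], fit$coef$ci_lo[2], fit$coef$ci_hi[2],
                    fit$coef$or[3], fit$sigma2_subject,
                    if (!fit$converged) " [convergence flagged]" else ""))
    write.table(fit$coef, sprintf("results/glmm_%s.tsv", oc), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
}

# pupil LMMs on trial-level window means (models 1-3)
tm$is_m <- as.numeric(tm$condition == "M")
m1 <- fit_pupil_lmm(tm[tm$condition %in% c("M", "NM"), ], "is_m")
tm$cat3 <- ifelse(tm$condition == "NM", "NM", tm$category)
m2 <- fit_pupil_lmm(tm[!is.na(tm$cat3) & tm$cat3 %in% c("NM", "CR", "RR", "NR"), ],
                    "cat3")
m3 <- fit_pupil_lmm(tm[tm$condition == "M" & !is.na(tm$m_order), ],
                    "m_order + confidence")
models <- rbind(
  cbind(model = "1_condition", m1$coef, icc = m1$icc),
  cbind(model = "2_report", m2$coef, icc = m2$icc),
  cbind(model = "3_order_conf", m3$coef, icc = m3$icc))
write.table(models, "results/lmm_models.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("LMM model 1: beta_M %.3f [%.3f, %.3f]; ICC %.3f / %.3f / %.3f",
                m1$coef$beta[2], m1$coef$ci_lo[2], m1$coef$ci_hi[2],
                m1$icc, m2$icc, m3$icc))
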