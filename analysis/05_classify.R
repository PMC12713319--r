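#!/usr/bin/env Rscript
# Leave-one-subject-out pupil classification.
#
# Classifies (a) trial condition (M vs NM) and (b) concurrent report within
# M-trials from trial-level 2-4 s window responses, using the midpoint of
# the two class means over all other subjects as the decision threshold,
# and tests pooled accuracy against the majority class proportion with an
# exact binomial test.

suppressMessages(library(pupilcb))

prep <- readRDS("scratch/prep_exp1.rds")
tm <- window_trial_means(prep)

cond <- tm[tm$condition %in% c("M", "NM"), ]
res_cond <- loso_classify(cond$value, cond$condition, cond$subject,
                          positive = "M")
message(sprintf("condition (M vs NM): %d/%d correct (%.1f%%), majority %.1f%%, p = %.2g",
                res_cond$n_correct, res_cond$n_total, 100 * res_cond$accuracy,
                100 * res_cond$p0, res_cond$p_value))

mtr <- tm[!is.na(tm$category) & tm$category != "EXCLUDED", ]
mtr$report <- ifelse(mtr$category == "CR", "CR", "NCR")
res_rep <- loso_classify(mtr$value, mtr$report, mtr$subject, positive = "CR")
message(sprintf("report (CR vs NCR within M): %d/%d correct (%.1f%%), majority %.1f%%, p = %.2g",
                res_rep$n_correct, res_rep$n_total, 100 * res_rep$accuracy,
                100 * res_rep$p0, res_rep$p_value))

out <- data.frame(
  target = c("condition_M_vs_NM", "report_CR_vs_NCR"),
  n_correct = c(res_cond$n_correct, res_rep$n_correct),
  n_total = c(res_cond$n_total, res_rep$n_total),
  accuracy = c(res_cond$accuracy, res_rep$accuracy),
  majority = c(res_cond$p0, res_rep$p0),
  p_binomial = c(res_cond$p_value, res_rep$p_value))
write.table(out, "results/classification.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/classification.tsv")
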