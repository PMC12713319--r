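#!/usr/bin/env Rscript
# Simulate the study cohort.
#
# One synthetic cohort emulating the first experiment: 41 participants, 30
# trials each (8 manipulated trials at the fixed positions 7, 10, 14, 16,
# 20, 22, 26, 29; 8 non-manipulated trials at random positions; 14 baseline
# trials), 1000 Hz pupil recordings with event-related dilation, drift,
# blinks and saccades, and coded concurrent/retrospective reports. Trial
# logs and ground truth go to results/; the full recordings (large) are
# kept as an R object under scratch/ for the downstream steps.

suppressMessages(library(pupilcb))

seed <- 20260930
cfg <- cb_config(profile = "exp1")
n_subjects <- 41

message("simulating ", n_subjects, " subjects (seed ", seed, ") ...")
cohort <- generate_cohort(cfg, n_subjects = n_subjects, seed = seed)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

trials <- do.call(rbind, lapply(names(cohort$subjects), function(id) {
  df <- as.data.frame(cohort$subjects[[id]]$trials)
  df$subject <- id
  df
}))
write.table(trials, "results/trials_all.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cohort$ground_truth, "results/ground_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(cohort, "scratch/cohort_exp1.rds")

gt <- cohort$ground_truth
m <- gt[gt$condition == "M", ]
message(sprintf("M-trials: %d; truly detected: %.1f%%; concurrently reported: %.1f%%",
                nrow(m), 100 * mean(m$detected), 100 * mean(m$reported_concurrent)))
message(sprintf("phenotypes: %s",
                paste(names(table(gt$phenotype[!duplicated(gt$subject)])),
                      table(gt$phenotype[!duplicated(gt$subject)]),
                      collapse = ", ")))
message("wrote results/trials_all.tsv, results/ground_truth.tsv, scratch/cohort_exp1.rds")
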