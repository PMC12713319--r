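#!/usr/bin/env Rscript
# Preprocess every recording and extract epochs.
#
# The chain per subject: linear blink interpolation with 150 ms padding,
# zero-phase 0.02-4 Hz third-order Butterworth band-pass, z-scoring to the
# session SD, decimation 1000 -> 100 Hz, regression of canonical pupil
# responses locked to blink/saccade ends, epoching -1..5 s around the test
# image with pre-stimulus baseline subtraction, and QC (trial dropped above
# 1/3 invalid samples; subject dropped at 15 of 30 trials).

suppressMessages(library(pupilcb))

cohort <- readRDS("scratch/cohort_exp1.rds")
message("preprocessing ", length(cohort$subjects), " subjects ...")
prep <- preprocess_cohort(cohort, drop_excluded = FALSE)

qc <- do.call(rbind, lapply(names(prep), function(id) {
  data.frame(subject = id,
             n_excluded_trials = prep[[id]]$qc$n_excluded,
             subject_excluded = prep[[id]]$qc$subject_excluded)
}))
write.table(qc, "results/qc_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
kept <- Filter(function(s) !s$qc$subject_excluded, prep)
message(sprintf("QC: %d/%d subjects kept; %d trials excluded in total",
                length(kept), length(prep), sum(qc$n_excluded_trials)))

# long-format epochs for the retained subjects
long <- do.call(rbind, lapply(names(kept), function(id) {
  ep <- kept[[id]]$epochs
  keep <- which(ep$included)
  data.frame(subject = id,
             trial_idx = rep(ep$trial_keys$trial_idx[keep], each = length(ep$time_s)),
             time_s = rep(ep$time_s, length(keep)),
             value = as.vector(t(ep$data[keep, , drop = FALSE])))
}))
con <- gzfile("scratch/epochs_long.tsv.gz", "w")
write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)
saveRDS(kept, "scratch/prep_exp1.rds")
message("wrote results/qc_report.tsv, scratch/epochs_long.tsv.gz, scratch/prep_exp1.rds")
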