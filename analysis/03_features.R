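#!/usr/bin/env Rscript
# Stage 3: extract the depression-biomarker feature table.
#
# Re-derives the resting epochs from the stored recordings and computes,
# per subject, delta-band power per channel, frontal alpha asymmetry,
# relative gamma power, delta-band correlation / coherence (magnitude and
# |imaginary part|) / PLV / PLI per channel pair, and per-channel HFD and
# DFA in the delta band. One row per subject; descriptors label every
# column. Written to results/features/features_rest.tsv.

library(vulneeg)

cohort_dir <- "results/cohort"
rec_dir <- "scratch/cohort"
out <- "results/features"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

subjects <- sub("^rest_", "", list.files(rec_dir, pattern = "^rest_"))
eps <- lapply(subjects, function(sid) {
  rec <- read_recording(file.path(rec_dir, paste0("rest_", sid)))
  rest_epochs(bandpass_filter(rec, 0.5, 40), 2)
})

t0 <- proc.time()[3]
ft <- extract_feature_table(
  eps,
  measures = c("band_power", "relative_power", "alpha_asymmetry",
               "correlation", "coherence_mag", "coherence_imag",
               "plv", "pli", "hfd", "dfa"),
  bands = c("delta", "alpha")
)
write_feature_table(ft, file.path(out, "features_rest.tsv"))

desc <- attr(ft, "descriptors")
cat(sprintf("feature table: %d subjects x %d features (%.0f s)\n",
            nrow(ft), nrow(desc), proc.time()[3] - t0))
print(table(desc$measure))
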