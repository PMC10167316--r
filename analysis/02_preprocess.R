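#!/usr/bin/env Rscript
# Stage 2: preprocess the simulated cohorts.
#
# Resting recordings: 0.5-40 Hz zero-phase band-pass, then consecutive 2 s
# pseudo-epochs. Task recordings: the full chain - filter, segment
# (-0.5..1.3 s around word onset), baseline-correct on the pre-stimulus
# interval, reject trials over 150 uV peak-to-peak, average re-reference
# over scalp channels, trim to the -0.2..1.3 s analysis window. Prints the
# per-subject rejection proportions and serialises the epoch counts.

library(vulneeg)

cohort_dir <- "results/cohort"
rec_dir <- "scratch/cohort"
out <- "results/preprocessed"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

events <- read_events(file.path(cohort_dir, "events.tsv"))
subjects <- sub("^rest_", "", list.files(rec_dir, pattern = "^rest_"))

summary_rows <- list()
for (sid in subjects) {
  rest <- read_recording(file.path(rec_dir, paste0("rest_", sid)))
  task <- read_recording(file.path(rec_dir, paste0("task_", sid)))
  rest_ep <- rest_epochs(bandpass_filter(rest, 0.5, 40), 2)
  res <- preprocess_recording(task, events)
  summary_rows[[sid]] <- data.frame(
    subject_id = sid, group = rest$group,
    n_rest_epochs = dim(rest_ep$data)[1],
    n_task_total = res$report$n_total,
    n_task_rejected = res$report$n_rejected,
    prop_rejected = round(res$report$proportion_rejected, 4)
  )
}
tab <- do.call(rbind, summary_rows)
utils::write.table(tab, file.path(out, "preprocess_summary.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("mean task rejection: %.1f%% (range %.1f-%.1f%%)\n",
            100 * mean(tab$prop_rejected), 100 * min(tab$prop_rejected),
            100 * max(tab$prop_rejected)))
print(tab, row.names = FALSE)
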