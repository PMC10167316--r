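#!/usr/bin/env Rscript
# Stage 6: classifier benchmarking.
#
# Windows the resting recordings (32-sample sequences, one per 2 s of
# signal) for the raw 0.5-40 Hz data and the delta band, and the task
# epochs for the raw data, then benchmarks all five families under the
# sample-level 60/20/20 split. A second pass contrasts sample-level vs
# subject-level splitting for the decision tree - the leakage comparison.
# Results land in results/classification/.

library(vulneeg)

out <- "results/classification"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260925L
cohort_dir <- "results/cohort"
rec_dir <- "scratch/cohort"

events <- read_events(file.path(cohort_dir, "events.tsv"))
subjects <- sub("^rest_", "", list.files(rec_dir, pattern = "^rest_"))

rest_eps <- lapply(subjects, function(sid) {
  rec <- read_recording(file.path(rec_dir, paste0("rest_", sid)))
  rest_epochs(bandpass_filter(rec, 0.5, 40), 2)
})
task_eps <- lapply(subjects, function(sid) {
  rec <- read_recording(file.path(rec_dir, paste0("task_", sid)))
  preprocess_recording(rec, events)$epochs
})

win <- function(eps, band = NULL, stride = 1024L) {
  bind_windows(lapply(eps, function(e) {
    if (!is.null(band)) e <- band_filter(e, band)
    window_sequences(e, window = 32L, stride = stride)
  }))
}
datasets <- list(
  rest_raw = win(rest_eps),
  rest_delta = win(rest_eps, "delta"),
  task_raw = win(task_eps, stride = 512L)
)
cat("windows per dataset:",
    paste(names(datasets), vapply(datasets, function(d) dim(d$X)[1], 0)),
    "\n")

models <- list(model_spec("dt"), model_spec("mlp"),
               model_spec("cnn1d"), model_spec("lstm"), model_spec("blstm"))
tab <- benchmark(datasets, models, split_spec("sample_level"), seed = seed)
utils::write.table(tab, file.path(out, "classification.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
print(tab, row.names = FALSE, digits = 3)

cat("\n== split-mode contrast (decision tree) ==\n")
contrast <- benchmark(datasets["rest_raw"],
                      list(model_spec("dt", max_depth = 10L)),
                      split_spec("subject_level"), seed = seed)
both <- rbind(tab[tab$family == "dt" & tab$dataset == "rest_raw", ], contrast)
utils::write.table(both, file.path(out, "split_contrast.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
print(both, row.names = FALSE, digits = 3)
cat("\nBoth split modes sit near chance here: a x1.5 delta-band effect at\n",
    "one channel is invisible inside 32-sample (62 ms) windows, and this\n",
    "generator gives subjects no idiosyncratic signatures for sample-level\n",
    "splits to exploit. When such signatures exist, sample-level splitting\n",
    "inflates accuracy while subject-level stays at chance - leakage_demo()\n",
    "demonstrates that directly (see the acceptance outputs).\n")
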