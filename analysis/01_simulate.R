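#!/usr/bin/env Rscript
# Stage 1: simulate the study cohorts.
#
# Builds a desk-scale synthetic version of the two-group design: a resting
# cohort and a SART task cohort of 8 + 8 subjects with a planted delta-band
# amplitude increase at O2 and a phase-lagged alpha coupling between F3 and
# P7 in the high-vulnerability group, plus Table-1-style questionnaire
# scores with the study's missingness (capped for the smaller cohort).
# Writes the event table, the questionnaire table and one recording
# container per subject (large binaries) under scratch/cohort/.

library(vulneeg)

out <- "results/cohort"
rec_dir <- "scratch/cohort"  # recordings are large binaries: scratch, not results
dir.create(rec_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260925L

effects <- effect_spec(
  amplitude = list(list(channel = "O2", band = "delta", factor = 1.5)),
  coupling = list(list(pair = c("F3", "P7"), band = "alpha",
                       phase_lag = pi / 2, mix = 0.6, group = "high"))
)
spec <- cohort_spec(n_high = 8, n_low = 8, rest_duration_s = 60,
                    effect = effects, seed = seed)

events <- generate_sart_events(n_blocks = 2, trials_per_block = 30,
                               probe_rate = 1 / 18, seed = seed)
write_events(events, file.path(out, "events.tsv"))
cat(sprintf("SART stream: %d trials, %d no-go, %d probe-labelled\n",
            nrow(events), sum(events$trial_type == "nogo"),
            sum(!is.na(events$stickiness_rating))))

rest <- generate_cohort(spec)
task_spec <- spec; task_spec$seed <- derive_seed(seed, 2)
task <- generate_cohort(task_spec, events = events)

write_questionnaires(rest$questionnaires, file.path(out, "questionnaires.tsv"))
for (r in rest$recordings) {
  write_recording(r, file.path(rec_dir, paste0("rest_", r$subject_id)), "bin")
}
for (r in task$recordings) {
  write_recording(r, file.path(rec_dir, paste0("task_", r$subject_id)), "bin")
}
cat(sprintf("wrote %d rest + %d task recordings (%g s at %g Hz)\n",
            length(rest$recordings), length(task$recordings),
            spec$rest_duration_s, spec$fs))
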