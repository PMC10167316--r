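#!/usr/bin/env Rscript
# Stage 5: evolutionary feature-subset selection.
#
# Runs grey wolf, genetic and particle swarm wrapper selection at the
# biomarker level (bits index whole measure-band blocks) over the resting
# feature table, with stratified 5-fold decision-tree accuracy as fitness.
# Prints the selected biomarker blocks and each optimizer's convergence
# trace; results serialized under results/selection/.

library(vulneeg)

out <- "results/selection"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260925L

ft <- read_feature_table("results/features/features_rest.tsv")

# Screen each biomarker family down to its strongest channels (largest |t|)
# before wrapper selection, mirroring the screening of significant channels
# that precedes subset selection; bits then index the screened families.
desc <- attr(ft, "descriptors")
keep <- unlist(lapply(split(desc$name, paste(desc$measure, desc$band)),
                      function(cols) {
  sub <- ft[, c("subject_id", "group", cols)]
  class(sub) <- class(ft)
  st <- channelwise_group_test(sub, 0.05)$stats
  st$feature[order(-abs(st$t))][seq_len(min(4, nrow(st)))]
}))
ft <- ft[, c("subject_id", "group", keep)]
attr(ft, "descriptors") <- vulneeg:::parse_descriptors(keep)
class(ft) <- c("feature_table", "data.frame")
cat(sprintf("screened to %d columns across %d biomarker families\n",
            length(keep),
            length(unique(paste(attr(ft, "descriptors")$measure,
                                attr(ft, "descriptors")$band)))))

for (alg in c("gwo", "ga", "pso")) {
  # small parsimony penalty: at equal accuracy, fewer biomarker blocks win
  cfg <- optimizer_config(alg, population = 10, iterations = 20,
                          seed = derive_seed(seed, match(alg, c("gwo", "ga",
                                                                "pso"))),
                          level = "biomarker", tree_depth = 5,
                          feature_penalty = 0.05)
  runner <- switch(alg, gwo = run_gwo, ga = run_ga, pso = run_pso)
  r <- runner(ft, cfg)
  write_selection_result(r, file.path(out, sprintf("selection_%s.tsv", alg)))
  cat(sprintf("%s: fitness %.3f with %d/%d biomarkers: %s\n", toupper(alg),
              r$best_fitness, r$n_selected, length(r$best_mask),
              paste(names(r$best_mask)[r$best_mask], collapse = ", ")))
  cat("   trace:", paste(sprintf("%.2f", r$trace), collapse = " "), "\n")
}
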