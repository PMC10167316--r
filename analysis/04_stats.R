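#!/usr/bin/env Rscript
# Stage 4: group statistics.
#
# (a) Questionnaire group comparison (pooled t-tests, NAs dropped) in the
#     style of a demographics table, plus the reference gender chi-square
#     for a 16/4 vs 9/11 female/male split.
# (b) Channel-wise pooled t-tests with BH-FDR (q = 0.05) per feature
#     family, with masked-t topography tables exported for plotting.

library(vulneeg)

out <- "results/stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

q <- read_questionnaires("results/cohort/questionnaires.tsv")
qt <- questionnaire_group_table(q)
utils::write.table(qt, file.path(out, "questionnaire_stats.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
cat("== questionnaire group comparison ==\n")
print(qt, row.names = FALSE, digits = 4)

gender <- matrix(c(16, 9, 4, 11), 2,
                 dimnames = list(group = c("high", "low"),
                                 gender = c("female", "male")))
cx <- chi2_2x2(gender, correction = "none")
cat(sprintf("\ngender split chi2 = %.2f (df = %d, p = %.3f)\n",
            cx$chi2, cx$df, cx$p))

ft <- read_feature_table("results/features/features_rest.tsv")
desc <- attr(ft, "descriptors")
mont <- build_montage()

cat("\n== channel-wise group tests (BH-FDR, q = 0.05) ==\n")
for (ms in c("band_power", "hfd", "dfa")) {
  cols <- desc$name[desc$measure == ms & desc$band == "delta"]
  sub <- ft[, c("subject_id", "group", cols)]
  class(sub) <- class(ft)
  g <- channelwise_group_test(sub, 0.05)
  export_topography(g, mont, file.path(out, sprintf("topo_%s_delta.tsv", ms)))
  sig <- g$stats$feature[g$stats$rejected]
  cat(sprintf("%-12s delta: %2d/32 significant (p* = %.3g)%s\n", ms,
              length(sig), g$p_threshold,
              if (length(sig)) paste0("  [", paste(sub("^.*\\|", "", sig),
                                                   collapse = ", "), "]")
              else ""))
}
for (bd in c("delta", "alpha")) {
  for (ms in c("pli", "plv", "correlation", "coherence_mag")) {
    cols <- desc$name[desc$measure == ms & desc$band == bd]
    sub <- ft[, c("subject_id", "group", cols)]
    class(sub) <- class(ft)
    g <- channelwise_group_test(sub, 0.05)
    sig <- sub("^.*\\|", "", g$stats$feature[g$stats$rejected])
    cat(sprintf("%-12s %-5s: %3d/%d pairs significant (p* = %.3g)%s\n", ms,
                bd, sum(g$stats$rejected), nrow(g$stats), g$p_threshold,
                if (length(sig) && length(sig) <= 6)
                  paste0("  [", paste(sig, collapse = ", "), "]") else ""))
  }
}
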