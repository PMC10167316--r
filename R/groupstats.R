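# Group-difference statistics: independent t-tests (from samples or printed
# summaries), 2x2 chi-square, Benjamini-Hochberg FDR, and channel-wise
# testing with topographic masking.

#' Independent two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] returning the `(t, df, p)` triple.
#' "pooled" assumes equal variances (df = n1 + n2 - 2); "welch" uses the
#' Welch-Satterthwaite correction. The sign of t follows
#' `mean(sample_a) - mean(sample_b)`.
#'
#' @param sample_a,sample_b numeric vectors (n >= 2 each; NA dropped).
#' @param variant "pooled" (default) or "welch".
#' @return list with `t`, `df`, `p`.
#' @export
ttest_independent <- function(sample_a, sample_b,
                              variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop_invalid("each sample needs n >= 2")
  }
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0 &&
      mean(sample_a) == mean(sample_b)) {
    stop_invalid("undefined statistic: both samples constant and equal")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = (variant == "pooled"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pooled t-test from printed summary statistics
#'
#' Reconstructs the pooled-variance independent t-test from group means,
#' SDs and sizes, as needed to check statistics reported only as summaries.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list with `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  for (v in list(n1 = n1, n2 = n2)) if (v < 2) stop_invalid("n must be >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop_invalid("sds must be > 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Chi-square test for a 2x2 contingency table
#'
#' Defaults to no continuity correction (the Pearson statistic
#' sum((O-E)^2/E) with df = 1).
#'
#' @param table 2x2 matrix of counts.
#' @param correction "none" (default) or "yates".
#' @return list with `chi2`, `df`, `p`.
#' @export
chi2_2x2 <- function(table, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2))
  if (any(table < 0)) stop_invalid("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_invalid("zero margin")
  }
  ht <- suppressWarnings(
    stats::chisq.test(table, correct = (correction == "yates"))
  )
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up procedure at level `q`: hypotheses with
#' `p <= p_threshold` are rejected, where `p_threshold` is the largest
#' p(i) (ascending) with `p(i) <= i*q/m`, or 0 when none qualifies.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @param q target FDR level (default 0.05).
#' @return list with `q`, `p_threshold`, `reject` (logical mask aligned
#'   with the input) and `n_rejected`.
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) stop_invalid("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_invalid("p-values must be in [0, 1]")
  }
  assert_scalar_num(q, "q", 1e-12, 1 - 1e-12)
  reject <- stats::p.adjust(pvalues, method = "BH") <= q
  p_threshold <- if (any(reject)) max(pvalues[reject]) else 0
  list(q = q, p_threshold = p_threshold, reject = reject,
       n_rejected = sum(reject))
}

#' Channel-wise (feature-wise) group test with FDR masking
#'
#' Pooled independent t-test of high versus low group for every feature
#' column, Benjamini-Hochberg correction across the tested family, and a
#' masked t-vector (t set to 0 where not significant) for topographic
#' plotting.
#'
#' @param ft a `feature_table` with a `group` column ("high"/"low").
#' @param q FDR level (default 0.05).
#' @param variant t-test variant (default "pooled").
#' @return A `group_stats` list: per-feature data.frame `stats`
#'   (`feature`, `t`, `df`, `p`, `rejected`, `masked_t`), plus `q` and
#'   `p_threshold`.
#' @export
channelwise_group_test <- function(ft, q = 0.05,
                                   variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  groups <- unique(ft$group)
  if (!all(c("high", "low") %in% groups)) {
    stop_invalid("both groups must be present")
  }
  hi <- ft$group == "high"; lo <- ft$group == "low"
  if (sum(hi) < 2 || sum(lo) < 2) stop_invalid("each group needs n >= 2")
  cols <- feature_columns(ft)
  res <- lapply(cols, function(cn) {
    tt <- ttest_independent(ft[[cn]][hi], ft[[cn]][lo], variant)
    data.frame(feature = cn, t = tt$t, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, res)
  fdr <- fdr_bh(stats_df$p, q)
  stats_df$rejected <- fdr$reject
  stats_df$masked_t <- ifelse(fdr$reject, stats_df$t, 0)
  structure(
    list(stats = stats_df, q = q, p_threshold = fdr$p_threshold),
    class = "group_stats"
  )
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats> %d features, %d significant at q = %g (p* = %.3g)\n",
              nrow(x$stats), sum(x$stats$rejected), x$q, x$p_threshold))
  invisible(x)
}

#' Export a channel topography table
#'
#' Writes one row per montage channel: position, t, p, masked t and the
#' rejection flag, in montage order. Features must be channel-level (their
#' descriptor location names a single channel).
#'
#' @param gsr a `group_stats` from [channelwise_group_test()].
#' @param montage an `eeg_montage`.
#' @param path output path (tab-separated).
#' @return The written data.frame, invisibly.
#' @export
export_topography <- function(gsr, montage, path) {
  loc <- sub("^[^|]*\\|[^|]*\\|", "", gsr$stats$feature)
  montage_check_channels(montage, loc)
  ord <- match(montage$channel_names, loc)
  ord <- ord[!is.na(ord)]
  df <- data.frame(
    channel = loc[ord],
    x = montage$positions[loc[ord], "x"],
    y = montage$positions[loc[ord], "y"],
    t = gsr$stats$t[ord],
    p = gsr$stats$p[ord],
    masked_t = gsr$stats$masked_t[ord],
    rejected = gsr$stats$rejected[ord],
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Questionnaire group comparison table
#'
#' Pooled t-tests of every questionnaire score between groups (NAs dropped
#' per score), formatted like a demographics table.
#'
#' @param q questionnaire data.frame from [generate_questionnaires()].
#' @return data.frame: score, per-group mean/sd/n, t, df, p.
#' @export
questionnaire_group_table <- function(q) {
  scores <- c("PTQ", "RRS", "CESD", "intensity", "frequency")
  hi <- q$group == "high"; lo <- q$group == "low"
  rows <- lapply(scores, function(sc) {
    a <- q[[sc]][hi]; b <- q[[sc]][lo]
    tt <- if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2) {
      ttest_independent(a, b, "pooled")
    } else list(t = NA_real_, df = NA_real_, p = NA_real_)
    data.frame(
      score = sc,
      mean_high = mean(a, na.rm = TRUE), sd_high = stats::sd(a, na.rm = TRUE),
      n_high = sum(!is.na(a)),
      mean_low = mean(b, na.rm = TRUE), sd_low = stats::sd(b, na.rm = TRUE),
      n_low = sum(!is.na(b)),
      t = tt$t, df = tt$df, p = tt$p,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
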