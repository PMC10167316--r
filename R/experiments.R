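# Seeded simulation experiments that probe whether the pipeline recovers
# what was planted and stays calibrated under the null. These drive the
# analysis scripts and the acceptance checks.

#' Planted delta-amplitude recovery experiment
#'
#' Simulates cohorts with a multiplicative delta-band amplitude effect at
#' one channel in the high-vulnerability group, runs the channel-wise
#' pooled t-test with BH-FDR over the 32-channel delta band-power family,
#' and records whether the planted channel lands in the rejected set.
#'
#' @param n_reps number of replicate cohorts (default 20).
#' @param seed base seed; replicate r uses `derive_seed(seed, r)`.
#' @param channel planted channel (default "O2").
#' @param factor amplitude factor for the high group (default 1.5).
#' @param n_high,n_low subjects per group (defaults 20).
#' @param rest_duration_s recording length per subject (default 20 s).
#' @param q FDR level (default 0.05).
#' @return list with `hits` (logical per replicate), `recovery_rate`.
#' @export
delta_effect_recovery <- function(n_reps = 20L, seed = 1L, channel = "O2",
                                  factor = 1.5, n_high = 20L, n_low = 20L,
                                  rest_duration_s = 20, q = 0.05) {
  target <- sprintf("band_power|delta|%s", channel)
  hits <- vapply(seq_len(n_reps), function(r) {
    eff <- effect_spec(amplitude = list(
      list(channel = channel, band = "delta", factor = factor)))
    spec <- cohort_spec(n_high = n_high, n_low = n_low,
                        rest_duration_s = rest_duration_s,
                        effect = eff, blink_rate = 0,
                        seed = derive_seed(seed, r))
    eps <- lapply(generate_cohort(spec)$recordings, rest_epochs, epoch_s = 2)
    ft <- extract_feature_table(eps, "band_power", "delta")
    g <- channelwise_group_test(ft, q)
    g$stats$rejected[g$stats$feature == target]
  }, NA)
  list(hits = hits, recovery_rate = mean(hits))
}

#' Planted phase-lag coupling contrast
#'
#' Simulates one cohort with a phase-lagged band-limited coupling planted
#' at a channel pair in the high group, computes each subject's PLI for
#' that pair, and tests (one-sided pooled t) whether the high group's PLI
#' exceeds the low group's.
#'
#' @param seed cohort seed.
#' @param pair channel pair (default F3-P7).
#' @param band coupling band (default "alpha").
#' @param phase_lag coupling lag in radians (default pi/2).
#' @param mix coupling strength relative to the background SD (default 0.6).
#' @param n_high,n_low subjects per group.
#' @param rest_duration_s recording length (default 12 s).
#' @return list with per-group mean PLI, the t statistic and the one-sided
#'   p-value.
#' @export
pli_coupling_contrast <- function(seed = 1L, pair = c("F3", "P7"),
                                  band = "alpha", phase_lag = pi / 2,
                                  mix = 0.6, n_high = 20L, n_low = 20L,
                                  rest_duration_s = 12) {
  eff <- effect_spec(coupling = list(
    list(pair = pair, band = band, phase_lag = phase_lag, mix = mix,
         group = "high")))
  spec <- cohort_spec(n_high = n_high, n_low = n_low,
                      rest_duration_s = rest_duration_s, effect = eff,
                      blink_rate = 0, seed = seed)
  coh <- generate_cohort(spec)
  pli_of <- function(rec) {
    ep <- rest_epochs(rec, 2)
    keep <- match(pair, ep$channel_names)
    ep$data <- ep$data[, keep, , drop = FALSE]
    ep$channel_names <- ep$channel_names[keep]
    ep$channel_roles <- ep$channel_roles[keep]
    connectivity_phase(ep, band)$pli$values[1, 2]
  }
  vals <- vapply(coh$recordings, pli_of, 0)
  grp <- vapply(coh$recordings, function(r) r$group, "")
  tt <- ttest_independent(vals[grp == "high"], vals[grp == "low"], "pooled")
  list(mean_high = mean(vals[grp == "high"]),
       mean_low = mean(vals[grp == "low"]),
       t = tt$t, p_one_sided = stats::pt(tt$t, tt$df, lower.tail = FALSE))
}

#' Null-cohort FDR calibration
#'
#' Replicated feature tables with no group effect are pushed through the
#' channel-wise test; the false-discovery proportion (all discoveries are
#' false under the null) is averaged over replicates. Benjamini-Hochberg
#' guarantees the expectation stays at or below q for independent features.
#'
#' @param n_reps replicates (default 200).
#' @param seed base seed.
#' @param n_features features per table (default 32).
#' @param n_per_group subjects per group (default 20).
#' @param q FDR level (default 0.05).
#' @return list with `fdp` per replicate and `empirical_fdr` (mean FDP).
#' @export
fdr_null_calibration <- function(n_reps = 200L, seed = 1L,
                                 n_features = 32L, n_per_group = 20L,
                                 q = 0.05) {
  fdp <- vapply(seq_len(n_reps), function(r) {
    X <- with_seed(derive_seed(seed, r), {
      matrix(stats::rnorm(2 * n_per_group * n_features), 2 * n_per_group)
    })
    cn <- sprintf("band_power|delta|f%03d", seq_len(n_features))
    colnames(X) <- cn
    ft <- data.frame(subject_id = sprintf("s%03d", seq_len(nrow(X))),
                     group = rep(c("high", "low"), each = n_per_group),
                     check.names = FALSE, stringsAsFactors = FALSE)
    ft <- cbind(ft, as.data.frame(X, check.names = FALSE))
    attr(ft, "descriptors") <- parse_descriptors(cn)
    class(ft) <- c("feature_table", "data.frame")
    g <- channelwise_group_test(ft, q)
    n_rej <- sum(g$stats$rejected)
    if (n_rej == 0) 0 else 1   # every rejection is a false discovery
  }, 0)
  list(fdp = fdp, empirical_fdr = mean(fdp))
}

#' Sample-level vs subject-level leakage demonstration
#'
#' Builds a windowed dataset with subject-specific nuisance signatures
#' (fixed per-channel offsets) and NO group effect, then evaluates a
#' decision tree under both split modes. Sample-level splitting lets the
#' classifier recognise subjects it has already seen, inflating accuracy
#' above chance; subject-level splitting stays at chance.
#'
#' @param seed base seed.
#' @param n_subjects_per_group subjects per group (default 10).
#' @param windows_per_subject windows per subject (default 20).
#' @param n_channels,window window dimensions (defaults 8, 16).
#' @param signature_sd SD of the per-subject channel offsets (default 1.5).
#' @return list with `acc_sample_level`, `acc_subject_level` and the
#'   chance-level binomial 99% interval half-widths.
#' @export
leakage_demo <- function(seed = 1L, n_subjects_per_group = 10L,
                         windows_per_subject = 20L, n_channels = 8L,
                         window = 16L, signature_sd = 1.5) {
  n_subj <- 2L * n_subjects_per_group
  n_win <- n_subj * windows_per_subject
  ds <- with_seed(derive_seed(seed, 17L), {
    X <- array(stats::rnorm(n_win * n_channels * window),
               c(n_win, n_channels, window))
    subj <- rep(seq_len(n_subj), each = windows_per_subject)
    for (s in seq_len(n_subj)) {
      sig <- stats::rnorm(n_channels, 0, signature_sd)
      X[subj == s, , ] <- X[subj == s, , , drop = FALSE] +
        rep(sig, each = windows_per_subject)
    }
    y <- as.integer(subj <= n_subjects_per_group)   # group = subject block
    structure(list(X = X, y = y, subject_id = sprintf("s%02d", subj),
                   window = window, stride = window),
              class = "windowed_dataset")
  })
  acc <- vapply(c("sample_level", "subject_level"), function(mode) {
    sp <- split_spec(mode, seed = derive_seed(seed, 23L))
    splits <- make_splits(ds, sp)
    train_eval(ds, model_spec("dt", max_depth = 10L), splits,
               seed = derive_seed(seed, 29L))$accuracy
  }, 0)
  list(acc_sample_level = acc[["sample_level"]],
       acc_subject_level = acc[["subject_level"]])
}
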