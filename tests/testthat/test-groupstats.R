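test_that("independent t-test matches hand computation and conventions", {
  r <- ttest_independent(c(1, 2, 3), c(4, 5, 6), "pooled")
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  same <- ttest_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(ttest_independent(c(1), c(2, 3)), "n >= 2")
  expect_error(ttest_independent(c(2, 2, 2), c(2, 2)), "undefined")
  # sign follows mean(a) - mean(b)
  expect_gt(ttest_independent(c(5, 6, 7), c(1, 2, 3))$t, 0)
})

test_that("summary-based t-test agrees with the sample-based one", {
  a <- exact_sample(20, 45.85, 4.70, seed = 1)
  b <- exact_sample(20, 25.10, 8.33, seed = 2)
  from_samples <- ttest_independent(a, b, "pooled")
  from_summary <- ttest_from_summary(45.85, 4.70, 20, 25.10, 8.33, 20)
  expect_equal(from_samples$t, from_summary$t, tolerance = 1e-9)
  expect_equal(from_samples$p, from_summary$p, tolerance = 1e-9)
  expect_equal(from_summary$df, 38)
  expect_equal(ttest_from_summary(5, 1, 10, 5, 1, 10)$t, 0)
  expect_error(ttest_from_summary(1, 0, 10, 2, 1, 10), "sds")
})

test_that("welch variant reduces df under unequal variances", {
  a <- exact_sample(10, 0, 1, seed = 3)
  b <- exact_sample(10, 1, 5, seed = 4)
  expect_lt(ttest_independent(a, b, "welch")$df,
            ttest_independent(a, b, "pooled")$df)
})

test_that("2x2 chi-square follows the Pearson formula", {
  expect_equal(chi2_2x2(matrix(c(10, 10, 10, 10), 2))$chi2, 0)
  r <- chi2_2x2(matrix(c(20, 10, 10, 20), 2))
  expect_equal(r$chi2, 6.667, tolerance = 1e-3)   # E = 15 in every cell
  expect_equal(r$df, 1)
  # Yates correction shrinks the statistic
  expect_lt(chi2_2x2(matrix(c(20, 10, 10, 20), 2), "yates")$chi2, r$chi2)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("BH step-up equals the brute-force definition", {
  set.seed(40)
  for (m in c(1, 5, 37, 200, 1000)) {
    p <- runif(m)^2
    r <- fdr_bh(p, 0.05)
    expect_identical(r$reject, bh_oracle(p, 0.05))
    expect_equal(r$n_rejected, sum(r$reject))
    if (r$n_rejected > 0) {
      expect_true(all(p[r$reject] <= r$p_threshold))
      expect_true(all(p[!r$reject] > r$p_threshold))
    } else {
      expect_equal(r$p_threshold, 0)
    }
  }
  expect_true(all(fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05), 0.05)$reject))
  expect_equal(fdr_bh(rep(1, 10), 0.05)$n_rejected, 0)
  expect_true(fdr_bh(0.01, 0.05)$reject)
  expect_error(fdr_bh(numeric(0)), "empty")
})

test_that("BH rejections are monotone in q", {
  set.seed(41)
  for (i in 1:20) {
    p <- runif(50)^3
    r1 <- fdr_bh(p, 0.01)$reject
    r5 <- fdr_bh(p, 0.05)$reject
    expect_true(all(r5[r1]))   # q = 0.01 rejections subset of q = 0.05
  }
})

test_that("channel-wise test recovers a planted feature and masks t", {
  set.seed(42)
  X <- matrix(rnorm(40 * 20), 40)
  X[1:20, 7] <- X[1:20, 7] + 2.5
  ft <- make_feature_table(X, rep(c("high", "low"), each = 20))
  g <- channelwise_group_test(ft, 0.05)
  expect_true(g$stats$rejected[7])
  expect_identical(g$stats$masked_t == 0, !g$stats$rejected)
  expect_equal(g$stats$df, rep(38, 20))
  # agrees feature-by-feature with ttest_independent
  tt <- ttest_independent(X[1:20, 7], X[21:40, 7], "pooled")
  expect_equal(g$stats$t[7], tt$t, tolerance = 1e-12)
  expect_error(channelwise_group_test(
    make_feature_table(X, rep("high", 40))), "both groups")
})

test_that("label permutations keep the familywise rejection rate near q", {
  set.seed(43)
  X <- matrix(rnorm(40 * 32), 40)
  groups <- rep(c("high", "low"), each = 20)
  any_rej <- replicate(200, {
    ft <- make_feature_table(X, sample(groups))
    channelwise_group_test(ft, 0.05)$stats |>
      (\(s) any(s$rejected))()
  })
  # under the global null the FDR bound caps the familywise false-discovery
  # proportion: expect few permutations with any rejection
  expect_lte(mean(any_rej), 0.10)
})

test_that("topography export preserves values and montage order", {
  set.seed(44)
  mont <- build_montage()
  X <- matrix(rnorm(20 * 32), 20)
  ft <- make_feature_table(X, rep(c("high", "low"), each = 10),
                           location = mont$channel_names)
  g <- channelwise_group_test(ft)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- export_topography(g, mont, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(back$channel, mont$channel_names)
  expect_equal(back$t, df$t, tolerance = 1e-12)
  expect_equal(back$masked_t, ifelse(back$rejected, back$t, 0))
  expect_equal(back$x, unname(mont$positions[, "x"]))
})

test_that("questionnaire table reports group summaries and pooled tests", {
  q <- generate_questionnaires(20, 20, seed = 50)
  tab <- questionnaire_group_table(q)
  expect_equal(tab$score, c("PTQ", "RRS", "CESD", "intensity", "frequency"))
  expect_equal(tab$df[1], 38)
  expect_equal(tab$n_high[4], 17)  # 3 missing writing ratings
  expect_equal(tab$df[4], 34)
  tt <- ttest_independent(q$PTQ[q$group == "high"], q$PTQ[q$group == "low"])
  expect_equal(tab$t[1], tt$t, tolerance = 1e-12)
})
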