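test_that("window cutting respects trial boundaries and the count formula", {
  ep <- make_epochs(array(seq_len(2 * 3 * 320), c(2, 3, 320)))
  ds <- window_sequences(ep, window = 32, stride = 32)
  expect_equal(dim(ds$X)[1], 2 * 10)   # 320/32 per trial
  # disjoint tiling: concatenated windows reproduce the trial
  expect_equal(as.vector(t(ds$X[1:10, 1, ])), as.vector(ep$data[1, 1, ]))
  for (L in c(100, 97)) {
    for (stride in c(7, 32)) {
      ep2 <- make_epochs(array(0, c(1, 2, L)))
      ds2 <- window_sequences(ep2, window = 32, stride = stride)
      expect_equal(dim(ds2$X)[1], floor((L - 32) / stride) + 1)
    }
  }
  expect_error(window_sequences(make_epochs(array(0, c(1, 2, 16))),
                                window = 32), "longer than")
})

test_that("windows carry the subject's group label", {
  spec <- cohort_spec(n_high = 1, n_low = 1, rest_duration_s = 4, seed = 12,
                      blink_rate = 0)
  coh <- generate_cohort(spec)
  ds <- bind_windows(lapply(coh$recordings, function(r) {
    window_sequences(rest_epochs(r, 2), window = 32)
  }))
  expect_setequal(unique(ds$y), c(0, 1))
  expect_true(all(ds$y[ds$subject_id == "high01"] == 1))
  expect_true(all(ds$y[ds$subject_id == "low01"] == 0))
  expect_equal(dim(ds$X)[2], 32)  # scalp channels only
})

test_that("sample-level splits stratify at the 60/20/20 ratios", {
  ds <- make_windowed(array(0, c(100, 1, 4)), rep(0:1, 50),
                      sprintf("s%02d", rep(1:10, each = 10)))
  sp <- split_spec("sample_level", seed = 13)
  splits <- make_splits(ds, sp)
  expect_length(splits$train, 60)
  expect_length(splits$val, 20)
  expect_length(splits$test, 20)
  expect_equal(sort(c(splits$train, splits$val, splits$test)), 1:100)
  expect_equal(sum(ds$y[splits$test]), 10)  # stratified
  folds <- make_splits(ds, split_spec("sample_level", k = 5, seed = 13),
                       kfold = TRUE)$folds
  expect_equal(as.vector(table(folds)), rep(20, 5))
})

test_that("subject-level splits never share a subject across partitions", {
  ds <- make_windowed(array(0, c(120, 1, 4)),
                      rep(rep(0:1, each = 6) , each = 10),
                      sprintf("s%02d", rep(1:12, each = 10)))
  splits <- make_splits(ds, split_spec("subject_level", seed = 14))
  for (pair in list(c("train", "val"), c("train", "test"), c("val", "test"))) {
    shared <- intersect(unique(ds$subject_id[splits[[pair[1]]]]),
                        unique(ds$subject_id[splits[[pair[2]]]]))
    expect_length(shared, 0)
  }
  tiny <- make_windowed(array(0, c(20, 1, 4)), rep(0:1, each = 10),
                        rep(c("a", "b"), each = 10))
  expect_error(make_splits(tiny, split_spec("subject_level")), "3 subjects")
})

test_that("decision tree separates well-separated Gaussian classes", {
  withr::with_seed(15, {
    X <- array(rnorm(200 * 2 * 8), c(200, 2, 8))
    y <- rep(0:1, each = 100)
    X[y == 1, 1, ] <- X[y == 1, 1, ] + 4
  })
  ds <- make_windowed(X, y, sprintf("s%02d", rep(1:20, each = 10)))
  splits <- make_splits(ds, split_spec("sample_level", seed = 16))
  rep_ <- train_eval(ds, model_spec("dt"), splits, seed = 17)
  expect_gte(rep_$accuracy, 0.95)
  # confusion matrix bookkeeping
  expect_equal(sum(rep_$confusion), length(splits$test))
  expect_equal(unname(rowSums(rep_$confusion)),
               as.vector(table(ds$y[splits$test])[c("0", "1")]))
})

test_that("k-fold evaluation pools predictions over disjoint folds", {
  withr::with_seed(18, {
    X <- matrix(rnorm(100 * 5), 100)
    y <- as.integer(X[, 2] > 0)
  })
  ds <- make_windowed(array(X, c(100, 5, 1)), y,
                      sprintf("s%02d", rep(1:10, each = 10)))
  folds <- make_splits(ds, split_spec("sample_level", k = 5, seed = 19),
                       kfold = TRUE)
  rep_ <- train_eval(ds, model_spec("dt"), folds, seed = 20)
  expect_equal(rep_$n_test, 100)
  expect_gte(rep_$accuracy, 0.9)
})

test_that("benchmark runs the dataset x model cross product, reproducibly", {
  withr::with_seed(21, {
    X <- array(rnorm(60 * 2 * 8), c(60, 2, 8))
    y <- rep(0:1, 30)
    X[y == 1, 1, ] <- X[y == 1, 1, ] + 3
  })
  ds <- make_windowed(X, y, sprintf("s%02d", rep(1:12, each = 5)))
  models <- list(model_spec("dt"), model_spec("mlp", max_epochs = 5L))
  t1 <- benchmark(list(a = ds, b = ds), models,
                  split_spec("sample_level"), seed = 22)
  t2 <- benchmark(list(a = ds, b = ds), models,
                  split_spec("sample_level"), seed = 22)
  expect_equal(nrow(t1), 4)
  expect_identical(t1, t2)
  expect_equal(nrow(benchmark(list(a = ds), list(),
                              split_spec("sample_level"))), 0)
})
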