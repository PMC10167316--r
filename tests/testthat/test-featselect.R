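# Small tables where a known subset of columns carries the class signal.
planted_table <- function(n = 60, d = 10, informative = 1:3, sep = 3,
                          seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * d), n)
    y <- rep(c("high", "low"), each = n / 2)
    for (j in informative) X[y == "high", j] <- X[y == "high", j] + sep
    make_feature_table(X, y, measure = sprintf("m%02d", seq_len(d)),
                       band = "delta")
  })
}

test_that("subset fitness scores separable features and empty masks", {
  ft <- planted_table(d = 5, informative = 1, sep = 6)
  mask1 <- c(TRUE, rep(FALSE, 4))
  f <- subset_fitness(ft, mask1, tree_depth = 3, seed = 2)
  expect_equal(f, 1.0)
  # lambda subtracts the selected fraction
  f_pen <- subset_fitness(ft, mask1, tree_depth = 3, lambda = 0.5, seed = 2)
  expect_equal(f_pen, 1.0 - 0.5 / 5)
  expect_equal(subset_fitness(ft, rep(FALSE, 5)), -2)
})

test_that("all-noise features score at chance level", {
  ft <- planted_table(n = 80, d = 6, informative = integer(0))
  accs <- vapply(1:5, function(s) {
    subset_fitness(ft, rep(TRUE, 6), tree_depth = 3, seed = s)
  }, 0)
  ci <- binom99(80, 0.5) / 80
  expect_gte(mean(accs), ci[1] - 0.1)
  expect_lte(mean(accs), ci[2] + 0.1)
})

test_that("fitness is deterministic given a seed", {
  ft <- planted_table()
  m <- rep(c(TRUE, FALSE), 5)
  expect_identical(subset_fitness(ft, m, seed = 9),
                   subset_fitness(ft, m, seed = 9))
})

test_that("all three optimizers select a single informative feature", {
  ft <- planted_table(d = 5, informative = 2, sep = 6)
  cfg <- function(alg) optimizer_config(alg, population = 8, iterations = 10,
                                        seed = 4, level = "column",
                                        tree_depth = 3)
  for (runner in list(run_gwo, run_ga, run_pso)) {
    r <- runner(ft, cfg("gwo"))
    expect_true(r$best_mask[2])
    expect_gte(r$best_fitness, 0.95)
    expect_gte(sum(r$best_mask), 1)
  }
})

test_that("optimizer traces are elitist (never worsen) and seeded", {
  ft <- planted_table()
  for (alg in c("gwo", "ga", "pso")) {
    cfg <- optimizer_config(alg, population = 6, iterations = 8, seed = 5,
                            level = "column", tree_depth = 3)
    runner <- switch(alg, gwo = run_gwo, ga = run_ga, pso = run_pso)
    r1 <- runner(ft, cfg)
    r2 <- runner(ft, cfg)
    expect_identical(r1$best_mask, r2$best_mask)
    expect_identical(r1$trace, r2$trace)
    expect_true(all(diff(r1$trace) >= 0))
    expect_equal(r1$best_fitness, max(r1$trace))
  }
})

test_that("degenerate GA and PSO dynamics freeze the population", {
  ft <- planted_table(d = 6)
  cfg_ga <- optimizer_config("ga", population = 6, iterations = 8, seed = 6,
                             level = "column", tree_depth = 3,
                             ga = list(crossover_prob = 0, mutation_prob = 0,
                                       tournament_size = 3))
  r <- run_ga(ft, cfg_ga)
  expect_true(all(r$trace == r$trace[1]))
  cfg_pso <- optimizer_config("pso", population = 6, iterations = 8,
                              seed = 6, level = "column", tree_depth = 3,
                              pso = list(inertia = 0, cognitive = 0,
                                         social = 0, v_max = 4))
  r <- run_pso(ft, cfg_pso)
  expect_true(all(r$trace == r$trace[1]))
})

test_that("biomarker-level bits expand to whole (measure, band) blocks", {
  # 3 biomarkers x 4 channels: informative block = biomarker 2
  withr::with_seed(7, {
    X <- matrix(rnorm(60 * 12), 60)
    y <- rep(c("high", "low"), each = 30)
    X[y == "high", 5:8] <- X[y == "high", 5:8] + 3
    meas <- rep(c("hfd", "pli", "dfa"), each = 4)
    loc <- rep(sprintf("ch%02d", 1:4), 3)
    ft <- make_feature_table(X, y, measure = meas, band = "delta",
                             location = loc)
  })
  cfg <- optimizer_config("gwo", population = 8, iterations = 10, seed = 8,
                          level = "biomarker", tree_depth = 3)
  r <- run_gwo(ft, cfg)
  expect_length(r$best_mask, 3)
  expect_named(r$best_mask, c("hfd|delta", "pli|delta", "dfa|delta"))
  expect_true(r$best_mask[["pli|delta"]])
})

test_that("optimizers approach the exhaustive-search optimum (d = 6)", {
  ft <- planted_table(n = 40, d = 6, informative = c(1, 4), sep = 2.5,
                      seed = 10)
  cfg0 <- optimizer_config("gwo", population = 8, iterations = 12,
                           level = "column", tree_depth = 3)
  ev <- vulneeg:::make_evaluator(ft, cfg0)
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 6)))[-1, ]
  best_exhaustive <- max(apply(masks, 1, ev$fitness))
  hits <- 0
  for (s in 1:3) {
    cfg <- cfg0; cfg$seed <- s
    if (run_gwo(ft, cfg)$best_fitness >= 0.95 * best_exhaustive) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 2)
})

test_that("selection results serialize with mask and trace", {
  ft <- planted_table(d = 4, informative = 1, sep = 5)
  r <- run_ga(ft, optimizer_config("ga", population = 6, iterations = 5,
                                   seed = 2, level = "column",
                                   tree_depth = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection_result(r, path)
  lines <- readLines(path)
  expect_true(any(grepl("^algorithm\tga$", lines)))
  expect_equal(sum(grepl("^\\d+\t", lines[- (1:which(lines == "[trace]"))])),
               length(r$trace))
})
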