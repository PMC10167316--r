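# Binary wrapper feature-subset selection. Candidate subsets are scored by
# the cross-validated accuracy of a Gini decision tree; three population
# metaheuristics (grey wolf, genetic, particle swarm) search the mask space.
# Continuous positions are mapped to bits through a sigmoid transfer with a
# 0.5 threshold (i.e. bit = position >= 0), the standard binary-GWO/PSO
# encoding.

#' Optimizer configuration
#'
#' @param algorithm "gwo", "ga" or "pso".
#' @param population population size (>= 2; default 10).
#' @param iterations iteration count (default 20).
#' @param seed integer seed; runs are deterministic per seed.
#' @param feature_penalty penalty weight lambda >= 0 on the fraction of
#'   selected bits (default 0: fitness is plain accuracy).
#' @param tree_depth decision-tree maximum depth for the fitness classifier
#'   (default 5; rpart caps depths at 30).
#' @param protocol "kfold" (stratified, default) or "holdout".
#' @param k folds for "kfold" (default 5).
#' @param holdout_frac test fraction for "holdout" (default 0.3).
#' @param level "biomarker" (default): bits index (measure, band) blocks of
#'   columns; "column": bits index single feature columns.
#' @param ga list: `crossover_prob`, `mutation_prob` (NULL = 1/d),
#'   `tournament_size`.
#' @param pso list: `inertia`, `cognitive`, `social`, `v_max`.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(algorithm = c("gwo", "ga", "pso"),
                             population = 10L, iterations = 20L, seed = 1L,
                             feature_penalty = 0, tree_depth = 5L,
                             protocol = c("kfold", "holdout"), k = 5L,
                             holdout_frac = 0.3,
                             level = c("biomarker", "column"),
                             ga = list(crossover_prob = 0.8,
                                       mutation_prob = NULL,
                                       tournament_size = 3L),
                             pso = list(inertia = 0.7, cognitive = 1.5,
                                        social = 1.5, v_max = 4)) {
  algorithm <- match.arg(algorithm)
  assert_scalar_num(population, "population", 2)
  assert_scalar_num(iterations, "iterations", 1)
  assert_scalar_num(feature_penalty, "feature_penalty", 0)
  structure(
    list(algorithm = algorithm, population = as.integer(population),
         iterations = as.integer(iterations), seed = as.integer(seed),
         feature_penalty = feature_penalty, tree_depth = as.integer(tree_depth),
         protocol = match.arg(protocol), k = as.integer(k),
         holdout_frac = holdout_frac, level = match.arg(level),
         ga = ga, pso = pso),
    class = "optimizer_config"
  )
}

# Stratified fold ids (1..k), or holdout partition (0 = train, 1 = test).
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

fit_tree_accuracy <- function(X, y, train, test, tree_depth) {
  depth <- min(tree_depth, 30L)
  df <- data.frame(.y = y, X, check.names = TRUE)
  fit <- rpart::rpart(.y ~ ., data = df[train, , drop = FALSE],
                      method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(maxdepth = depth,
                                                     minsplit = 4, cp = 0,
                                                     xval = 0))
  pred <- predict(fit, df[test, , drop = FALSE], type = "class")
  mean(pred == y[test])
}

#' Fitness of a feature subset
#'
#' Accuracy of a Gini decision tree on the selected columns under the
#' evaluation protocol, minus `lambda` times the fraction of selected bits.
#' An empty mask returns the defined worst fitness (-2) rather than an
#' error, so optimizers can traverse it.
#'
#' @param ft a `feature_table`.
#' @param mask logical vector over feature columns.
#' @param protocol "kfold" or "holdout".
#' @param tree_depth tree depth (default 5).
#' @param lambda feature-count penalty weight.
#' @param k folds (default 5).
#' @param holdout_frac holdout test fraction.
#' @param seed seed controlling the partition.
#' @param folds optional precomputed fold ids (overrides seed).
#' @return Scalar fitness.
#' @export
subset_fitness <- function(ft, mask, protocol = c("kfold", "holdout"),
                           tree_depth = 5L, lambda = 0, k = 5L,
                           holdout_frac = 0.3, seed = 1L, folds = NULL) {
  protocol <- match.arg(protocol)
  cols <- feature_columns(ft)
  stopifnot(length(mask) == length(cols))
  if (!any(mask)) return(-2)
  X <- as.matrix(ft[, cols[mask], drop = FALSE])
  y <- factor(ft$group)
  if (is.null(folds)) {
    folds <- with_seed(seed, {
      if (protocol == "kfold") stratified_folds(y, k)
      else as.integer(stratified_folds(y, round(1 / holdout_frac)) == 1)
    })
  }
  acc <- if (protocol == "kfold") {
    correct <- 0
    for (f in sort(unique(folds))) {
      te <- which(folds == f); tr <- which(folds != f)
      correct <- correct +
        fit_tree_accuracy(X, y, tr, te, tree_depth) * length(te)
    }
    correct / length(y)
  } else {
    fit_tree_accuracy(X, y, which(folds == 0), which(folds == 1), tree_depth)
  }
  acc - lambda * mean(mask)
}

# Bits indexed by the configured level; returns list(bit_names, expand(mask))
# where expand maps bit masks to column masks.
selection_bits <- function(ft, level) {
  desc <- attr(ft, "descriptors")
  if (level == "column") {
    list(names = desc$name, expand = function(m) m)
  } else {
    key <- paste(desc$measure, desc$band, sep = "|")
    ukey <- unique(key)
    list(names = ukey,
         expand = function(m) key %in% ukey[m])
  }
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Shared scaffolding: evaluates bit masks, tracks the elitist best, builds
# the SelectionResult.
make_evaluator <- function(ft, config) {
  bits <- selection_bits(ft, config$level)
  y <- factor(ft$group)
  folds <- with_seed(derive_seed(config$seed, 7L), {
    if (config$protocol == "kfold") stratified_folds(y, config$k)
    else as.integer(stratified_folds(y, round(1 / config$holdout_frac)) == 1)
  })
  fit_fun <- function(mask) {
    subset_fitness(ft, bits$expand(mask), protocol = config$protocol,
                   tree_depth = config$tree_depth,
                   lambda = config$feature_penalty, k = config$k,
                   holdout_frac = config$holdout_frac, folds = folds)
  }
  list(bits = bits, fitness = fit_fun, d = length(bits$names))
}

finish_selection <- function(best_mask, best_fit, trace, config, bit_names) {
  names(best_mask) <- bit_names
  structure(
    list(best_mask = best_mask, best_fitness = best_fit, trace = trace,
         n_selected = sum(best_mask), config = config, seed = config$seed),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: fitness %.4f with %d/%d bits\n",
              x$config$algorithm, x$best_fitness, x$n_selected,
              length(x$best_mask)))
  invisible(x)
}

#' Grey wolf optimizer for feature selection
#'
#' Continuous wolf positions move toward the three best wolves (alpha, beta,
#' delta) with the exploration parameter `a` decreasing linearly from 2 to
#' 0; bits are read off through the sigmoid transfer. The best mask ever
#' evaluated is retained (elitism), so the best-fitness trace never worsens.
#'
#' @param ft a `feature_table`.
#' @param config an [optimizer_config()] (its `algorithm` field is ignored).
#' @return A `selection_result`: `best_mask` (named logical), `best_fitness`,
#'   per-iteration `trace`, `n_selected`, `config`, `seed`.
#' @export
run_gwo <- function(ft, config = optimizer_config("gwo")) {
  ev <- make_evaluator(ft, config)
  np <- config$population; d <- ev$d
  with_seed(config$seed, {
    X <- matrix(stats::runif(np * d, -1, 1), np, d)
    X[1, ] <- abs(X[1, ])  # guarantee one all-on wolf
    to_mask <- function(x) sigmoid(x) >= 0.5
    fit <- apply(X, 1, function(x) ev$fitness(to_mask(x)))
    best_i <- which.max(fit)
    best_mask <- to_mask(X[best_i, ]); best_fit <- fit[best_i]
    trace <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      a <- 2 * (1 - (it - 1) / max(1, config$iterations - 1))
      ord <- order(fit, decreasing = TRUE)
      leaders <- X[ord[seq_len(min(3, np))], , drop = FALSE]
      for (w in seq_len(np)) {
        xs <- matrix(0, nrow(leaders), d)
        for (l in seq_len(nrow(leaders))) {
          r1 <- stats::runif(d); r2 <- stats::runif(d)
          A <- 2 * a * r1 - a; C <- 2 * r2
          xs[l, ] <- leaders[l, ] - A * abs(C * leaders[l, ] - X[w, ])
        }
        X[w, ] <- colMeans(xs)
      }
      fit <- apply(X, 1, function(x) ev$fitness(to_mask(x)))
      i <- which.max(fit)
      if (fit[i] > best_fit) {
        best_fit <- fit[i]; best_mask <- to_mask(X[i, ])
      }
      trace[it] <- best_fit
    }
    finish_selection(best_mask, best_fit, trace, config, ev$bits$names)
  })
}

#' Genetic algorithm for feature selection
#'
#' Tournament selection, one-point crossover, per-bit mutation and elitism
#' of one.
#'
#' @inheritParams run_gwo
#' @return A `selection_result`.
#' @export
run_ga <- function(ft, config = optimizer_config("ga")) {
  ev <- make_evaluator(ft, config)
  np <- config$population; d <- ev$d
  pc <- config$ga$crossover_prob
  pm <- if (is.null(config$ga$mutation_prob)) 1 / d else config$ga$mutation_prob
  ts <- config$ga$tournament_size
  with_seed(config$seed, {
    P <- matrix(stats::runif(np * d) < 0.5, np, d)
    P[1, ] <- TRUE
    fit <- apply(P, 1, ev$fitness)
    best_i <- which.max(fit)
    best_mask <- P[best_i, ]; best_fit <- fit[best_i]
    trace <- numeric(config$iterations)
    tournament <- function() {
      cand <- sample.int(np, min(ts, np))
      cand[which.max(fit[cand])]
    }
    for (it in seq_len(config$iterations)) {
      newP <- P
      newP[1, ] <- P[which.max(fit), ]  # elitism
      w <- 2
      while (w <= np) {
        p1 <- P[tournament(), ]; p2 <- P[tournament(), ]
        if (stats::runif(1) < pc && d > 1) {
          cut <- sample.int(d - 1, 1)
          c1 <- c(p1[seq_len(cut)], p2[(cut + 1):d])
          c2 <- c(p2[seq_len(cut)], p1[(cut + 1):d])
        } else {
          c1 <- p1; c2 <- p2
        }
        if (pm > 0) {
          flip1 <- stats::runif(d) < pm; c1[flip1] <- !c1[flip1]
          flip2 <- stats::runif(d) < pm; c2[flip2] <- !c2[flip2]
        }
        newP[w, ] <- c1
        if (w + 1 <= np) newP[w + 1, ] <- c2
        w <- w + 2
      }
      P <- newP
      fit <- apply(P, 1, ev$fitness)
      i <- which.max(fit)
      if (fit[i] > best_fit) { best_fit <- fit[i]; best_mask <- P[i, ] }
      trace[it] <- best_fit
    }
    finish_selection(best_mask, best_fit, trace, config, ev$bits$names)
  })
}

#' Particle swarm optimizer for feature selection
#'
#' Velocity update with inertia, cognitive and social terms (global-best
#' topology), velocities clamped to `v_max`; bits via the sigmoid transfer
#' on positions.
#'
#' @inheritParams run_gwo
#' @return A `selection_result`.
#' @export
run_pso <- function(ft, config = optimizer_config("pso")) {
  ev <- make_evaluator(ft, config)
  np <- config$population; d <- ev$d
  pp <- config$pso
  with_seed(config$seed, {
    X <- matrix(stats::runif(np * d, -1, 1), np, d)
    X[1, ] <- abs(X[1, ])
    V <- matrix(0, np, d)
    to_mask <- function(x) sigmoid(x) >= 0.5
    fit <- apply(X, 1, function(x) ev$fitness(to_mask(x)))
    pbest <- X; pbest_fit <- fit
    g <- which.max(fit)
    best_mask <- to_mask(X[g, ]); best_fit <- fit[g]
    gbest <- X[g, ]
    trace <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      for (w in seq_len(np)) {
        r1 <- stats::runif(d); r2 <- stats::runif(d)
        V[w, ] <- pp$inertia * V[w, ] +
          pp$cognitive * r1 * (pbest[w, ] - X[w, ]) +
          pp$social * r2 * (gbest - X[w, ])
        V[w, ] <- pmax(pmin(V[w, ], pp$v_max), -pp$v_max)
        X[w, ] <- X[w, ] + V[w, ]
      }
      fit <- apply(X, 1, function(x) ev$fitness(to_mask(x)))
      upd <- fit > pbest_fit
      pbest[upd, ] <- X[upd, ]; pbest_fit[upd] <- fit[upd]
      g <- which.max(pbest_fit)
      gbest <- pbest[g, ]
      if (pbest_fit[g] > best_fit) {
        best_fit <- pbest_fit[g]; best_mask <- to_mask(pbest[g, ])
      }
      trace[it] <- best_fit
    }
    finish_selection(best_mask, best_fit, trace, config, ev$bits$names)
  })
}

#' Serialize a selection result
#'
#' Structured text: header lines (algorithm, fitness, seed), the mask by
#' bit name, and the fitness trace.
#'
#' @param sr a `selection_result`.
#' @param path output path.
#' @export
write_selection_result <- function(sr, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("algorithm\t%s", sr$config$algorithm),
    sprintf("best_fitness\t%.6f", sr$best_fitness),
    sprintf("n_selected\t%d", sr$n_selected),
    sprintf("seed\t%d", sr$seed),
    "[mask]"
  ), con)
  writeLines(sprintf("%s\t%d", names(sr$best_mask),
                     as.integer(sr$best_mask)), con)
  writeLines("[trace]", con)
  writeLines(sprintf("%d\t%.6f", seq_along(sr$trace), sr$trace), con)
  invisible(path)
}
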