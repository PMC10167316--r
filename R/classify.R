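# Classifier benchmarking at desk scale: decision tree plus the neural
# families from nn.R, with sample-level (window-stratified) and
# subject-level (whole-subject) validation splits.

#' Model specification
#'
#' Hyperparameter bundles per classifier family. Defaults: DT depth 3 with
#' Gini impurity; MLP with hidden layers 16/8; 1-D CNN with two valid
#' convolution blocks (32/64 filters, kernel 3) and global average pooling;
#' LSTM hidden 24; BLSTM hidden 16 per direction with a 16-unit dense head.
#' All neural families train with Adam (lr 0.001, beta1 0.9, beta2 0.999),
#' batch size 32, early stopping on validation loss (patience 5, up to 50
#' epochs).
#'
#' @param family "dt", "mlp", "cnn1d", "lstm" or "blstm".
#' @param ... overrides of the family defaults (e.g. `max_depth`, `hidden`,
#'   `filters`, `kernel`, `hidden_lstm`, `head`, `learning_rate`,
#'   `batch_size`, `max_epochs`, `patience`, `beta1`, `beta2`).
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("dt", "mlp", "cnn1d", "lstm", "blstm"),
                       ...) {
  family <- match.arg(family)
  defaults <- list(
    dt = list(max_depth = 3L),
    mlp = list(hidden = c(16L, 8L)),
    cnn1d = list(filters = c(32L, 64L), kernel = 3L),
    lstm = list(hidden_lstm = 24L, head = integer(0)),
    blstm = list(hidden_lstm = 16L, head = 16L)
  )[[family]]
  common <- list(learning_rate = 0.001, batch_size = 32L, max_epochs = 50L,
                 patience = 5L, beta1 = 0.9, beta2 = 0.999)
  spec <- utils::modifyList(c(defaults, common), list(...))
  spec$family <- family
  class(spec) <- "model_spec"
  spec
}

#' Cut fixed-length windows from epochs or a recording
#'
#' Windows are cut per trial and never cross trial boundaries; each window
#' inherits the source subject's group label and subject id. A continuous
#' recording is treated as a single trial.
#'
#' @param x an `eeg_epochs` or `eeg_recording`.
#' @param window window length in samples (default 32).
#' @param stride hop in samples (default = window: disjoint tiling).
#' @param scalp_only use scalp channels only (default TRUE).
#' @return A `windowed_dataset`: list with `X` (array windows x channels x
#'   window), `y` (0 = low, 1 = high), `subject_id`, `window`, `stride`.
#' @export
window_sequences <- function(x, window = 32L, stride = window,
                             scalp_only = TRUE) {
  assert_scalar_num(window, "window", 1)
  assert_scalar_num(stride, "stride", 1)
  window <- as.integer(window); stride <- as.integer(stride)
  if (inherits(x, "eeg_recording")) {
    d3 <- array(x$data, c(1, nrow(x$data), ncol(x$data)))
    trials <- 1L
    n_t <- ncol(x$data)
    roles <- x$channel_roles
    subject <- x$subject_id; group <- x$group
  } else if (inherits(x, "eeg_epochs")) {
    d3 <- x$data
    trials <- dim(d3)[1]
    n_t <- dim(d3)[3]
    roles <- x$channel_roles
    subject <- x$subject_id; group <- x$group
  } else stop_invalid("expected eeg_epochs or eeg_recording")
  if (window > n_t) stop_invalid("window (%d) longer than signal (%d)",
                                 window, n_t)
  chan <- if (scalp_only) which(roles == "scalp") else seq_along(roles)
  per_trial <- floor((n_t - window) / stride) + 1L
  n_win <- trials * per_trial
  X <- array(0, c(n_win, length(chan), window))
  wi <- 0L
  for (tr in seq_len(trials)) {
    for (w in seq_len(per_trial)) {
      s <- (w - 1L) * stride
      wi <- wi + 1L
      X[wi, , ] <- d3[tr, chan, (s + 1):(s + window)]
    }
  }
  structure(
    list(X = X, y = rep(as.integer(group == "high"), n_win),
         subject_id = rep(subject, n_win), window = window, stride = stride),
    class = "windowed_dataset"
  )
}

#' Concatenate windowed datasets across subjects
#' @param ds_list list of `windowed_dataset`s.
#' @return A single `windowed_dataset`.
#' @export
bind_windows <- function(ds_list) {
  X <- do.call(abind3, lapply(ds_list, `[[`, "X"))
  structure(
    list(X = X, y = unlist(lapply(ds_list, `[[`, "y")),
         subject_id = unlist(lapply(ds_list, `[[`, "subject_id")),
         window = ds_list[[1]]$window, stride = ds_list[[1]]$stride),
    class = "windowed_dataset"
  )
}

abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    np <- dim(p)[1]
    if (np > 0) out[(at + 1):(at + np), , ] <- p
    at <- at + np
  }
  out
}

#' Split specification
#'
#' @param mode "sample_level" (windows stratified by class; leak-prone when
#'   windows from one subject land in several partitions) or
#'   "subject_level" (whole subjects assigned to one partition).
#' @param ratios train/val/test fractions summing to 1 (default 60/20/20).
#' @param k folds for k-fold mode (default 5).
#' @param seed integer seed.
#' @return A `split_spec` list.
#' @export
split_spec <- function(mode = c("sample_level", "subject_level"),
                       ratios = c(0.6, 0.2, 0.2), k = 5L, seed = 1L) {
  mode <- match.arg(mode)
  if (any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-9) {
    stop_invalid("ratios must be positive and sum to 1")
  }
  structure(list(mode = mode, ratios = ratios, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Build train/val/test partitions or k folds
#'
#' @param ds a `windowed_dataset`.
#' @param spec a [split_spec()].
#' @param kfold if TRUE return fold ids instead of a 3-way partition.
#' @return For 3-way: list with integer index vectors `train`, `val`,
#'   `test`. For k-fold: list with `folds` (fold id per window).
#' @export
make_splits <- function(ds, spec, kfold = FALSE) {
  n <- length(ds$y)
  if (n == 0) stop_invalid("empty dataset")
  with_seed(spec$seed, {
    if (spec$mode == "sample_level") {
      if (kfold) return(list(folds = stratified_folds(factor(ds$y), spec$k)))
      idx <- integer(n)  # 1 train, 2 val, 3 test
      for (cl in unique(ds$y)) {
        who <- sample(which(ds$y == cl))
        m <- length(who)
        n_tr <- round(spec$ratios[1] * m)
        n_va <- round(spec$ratios[2] * m)
        idx[who[seq_len(n_tr)]] <- 1L
        idx[who[(n_tr + 1):(n_tr + n_va)]] <- 2L
        idx[who[(n_tr + n_va + 1):m]] <- 3L
      }
    } else {
      subj <- unique(ds$subject_id)
      subj_y <- ds$y[match(subj, ds$subject_id)]
      if (min(table(subj_y)) < 3 && !kfold) {
        stop_invalid("subject_level split needs >= 3 subjects per class")
      }
      assign_s <- integer(length(subj))
      for (cl in unique(subj_y)) {
        who <- sample(which(subj_y == cl))
        m <- length(who)
        if (kfold) {
          assign_s[who] <- rep_len(seq_len(spec$k), m)
        } else {
          n_tr <- max(1, round(spec$ratios[1] * m))
          n_va <- max(1, round(spec$ratios[2] * m))
          n_tr <- min(n_tr, m - 2)
          grp <- c(rep(1L, n_tr), rep(2L, n_va), rep(3L, m - n_tr - n_va))
          assign_s[who] <- grp[seq_len(m)]
        }
      }
      idx <- assign_s[match(ds$subject_id, subj)]
      if (kfold) return(list(folds = idx))
    }
    list(train = which(idx == 1L), val = which(idx == 2L),
         test = which(idx == 3L))
  })
}

eval_report <- function(y_true, y_pred, seed = NA_integer_) {
  cm <- table(factor(y_true, levels = c(0, 1)),
              factor(y_pred, levels = c(0, 1)))
  cm <- matrix(as.numeric(cm), 2, 2,
               dimnames = list(true = c("low", "high"),
                               pred = c("low", "high")))
  per_class <- function(cl) {
    tp <- cm[cl, cl]
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else NA_real_
    rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else NA_real_
    c(precision = prec, recall = rec, f1 = f1)
  }
  structure(
    list(accuracy = sum(diag(cm)) / sum(cm), confusion = cm,
         low = per_class("low"), high = per_class("high"),
         n_test = sum(cm), seed = seed),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f on %d test samples\n",
              x$accuracy, x$n_test))
  print(x$confusion)
  invisible(x)
}

flatten_X <- function(X) {
  if (is.matrix(X)) X else matrix(X, dim(X)[1], dim(X)[2] * dim(X)[3])
}

dt_train_predict <- function(spec, Xtr, ytr, Xte) {
  df_tr <- data.frame(.y = factor(ytr, levels = c(0, 1)), Xtr,
                      check.names = TRUE)
  fit <- rpart::rpart(.y ~ ., df_tr, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        maxdepth = min(spec$max_depth, 30L),
                        minsplit = 4, cp = 0, xval = 0))
  as.integer(as.character(
    predict(fit, data.frame(Xte, check.names = TRUE), type = "class")))
}

#' Train a classifier and evaluate it
#'
#' For "dt" and "mlp" with k-fold splits: trains on k-1 folds and pools
#' held-out predictions (MLP trains without early stopping there). For
#' 3-way splits: fits on train, uses val for early stopping of neural
#' families, and reports test-set metrics. Deterministic per seed.
#'
#' @param ds a `windowed_dataset`.
#' @param model a [model_spec()].
#' @param splits output of [make_splits()].
#' @param seed integer seed for weight init and batch order.
#' @return An `eval_report` (accuracy, 2x2 confusion matrix, per-class
#'   precision/recall/F1).
#' @export
train_eval <- function(ds, model, splits, seed = 1L) {
  stopifnot(inherits(model, "model_spec"))
  if (any(!is.finite(ds$X))) stop_invalid("non-finite values in input")
  flat <- model$family %in% c("dt", "mlp")
  Xall <- if (flat) flatten_X(ds$X) else ds$X
  if (!is.null(splits$folds)) {
    preds <- integer(length(ds$y))
    for (f in sort(unique(splits$folds))) {
      te <- which(splits$folds == f); tr <- which(splits$folds != f)
      preds[te] <- fit_predict_family(model, Xall, ds$y, tr, te, NULL,
                                      derive_seed(seed, f))
    }
    eval_report(ds$y, preds, seed)
  } else {
    preds <- fit_predict_family(model, Xall, ds$y, splits$train,
                                splits$test, splits$val, seed)
    eval_report(ds$y[splits$test], preds, seed)
  }
}

fit_predict_family <- function(model, X, y, train, test, val, seed) {
  if (model$family == "dt") {
    return(dt_train_predict(model, X[train, , drop = FALSE], y[train],
                            X[test, , drop = FALSE]))
  }
  Xtr <- slice_batch(X, train)
  Xva <- if (!is.null(val) && length(val)) slice_batch(X, val) else NULL
  fitted <- nn_train(model$family, model, Xtr, y[train],
                     X_val = Xva, y_val = if (is.null(Xva)) NULL else y[val],
                     seed = seed)
  as.integer(fitted$predict(fitted$params, slice_batch(X, test)) >= 0.5)
}

#' Benchmark model families across band-specific datasets
#'
#' Cross-product of datasets and models under shared seeds; returns a tidy
#' results table.
#'
#' @param datasets named list of `windowed_dataset`s (e.g. one per band).
#' @param models list of [model_spec()]s.
#' @param spec a [split_spec()].
#' @param seed integer seed shared across cells.
#' @param kfold use k-fold evaluation (default FALSE: 60/20/20).
#' @return data.frame: dataset, family, split mode, seed, accuracy,
#'   precision/recall/F1 of the "high" class.
#' @export
benchmark <- function(datasets, models, spec = split_spec(), seed = 1L,
                      kfold = FALSE) {
  rows <- list()
  for (dn in names(datasets)) {
    ds <- datasets[[dn]]
    sp <- spec; sp$seed <- derive_seed(seed, match(dn, names(datasets)))
    splits <- make_splits(ds, sp, kfold = kfold)
    for (mo in models) {
      rep_ <- train_eval(ds, mo, splits, seed = sp$seed)
      rows[[length(rows) + 1]] <- data.frame(
        dataset = dn, family = mo$family, mode = sp$mode, seed = sp$seed,
        accuracy = rep_$accuracy,
        precision_high = rep_$high[["precision"]],
        recall_high = rep_$high[["recall"]],
        f1_high = rep_$high[["f1"]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(dataset = character(0), family = character(0),
                      mode = character(0), seed = integer(0),
                      accuracy = numeric(0), precision_high = numeric(0),
                      recall_high = numeric(0), f1_high = numeric(0)))
  }
  do.call(rbind, rows)
}
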