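# Minimal neural engine for the desk-scale classifier families: MLP,
# 1-D CNN, LSTM and bidirectional LSTM, trained with Adam on the binary
# cross-entropy of a single sigmoid output unit. Forward and backward passes
# are written explicitly (no autograd) and are checked against finite
# differences in the test suite. Everything is seeded and deterministic.

relu <- function(x) pmax(x, 0)

# Stable BCE on logits; returns loss and dL/dz (mean-reduced).
bce_logits <- function(z, y) {
  p <- 1 / (1 + exp(-z))
  loss <- mean(ifelse(z > 0, z - y * z + log1p(exp(-z)),
                      log1p(exp(z)) - y * z))
  list(loss = loss, dz = (p - y) / length(y), p = p)
}

glorot <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / (n_in + n_out))), n_in, n_out)
}

# --- MLP ------------------------------------------------------------------

mlp_init <- function(d, hidden) {
  sizes <- c(d, hidden, 1L)
  params <- list()
  for (l in seq_len(length(sizes) - 1)) {
    params[[paste0("W", l)]] <- glorot(sizes[l], sizes[l + 1])
    params[[paste0("b", l)]] <- matrix(0, 1, sizes[l + 1])
  }
  params
}

mlp_forward <- function(params, X) {
  nl <- length(params) / 2
  A <- list(X)
  for (l in seq_len(nl)) {
    Z <- A[[l]] %*% params[[paste0("W", l)]] +
      matrix(params[[paste0("b", l)]], nrow(X), ncol(params[[paste0("W", l)]]),
             byrow = TRUE)
    A[[l + 1]] <- if (l < nl) relu(Z) else Z
  }
  list(z = A[[nl + 1]][, 1], A = A)
}

mlp_fwd_bwd <- function(params, X, y) {
  nl <- length(params) / 2
  fw <- mlp_forward(params, X)
  lo <- bce_logits(fw$z, y)
  grads <- params
  dZ <- matrix(lo$dz, ncol = 1)
  for (l in nl:1) {
    A_prev <- fw$A[[l]]
    grads[[paste0("W", l)]] <- crossprod(A_prev, dZ)
    grads[[paste0("b", l)]] <- matrix(colSums(dZ), 1)
    if (l > 1) {
      dA <- dZ %*% t(params[[paste0("W", l)]])
      dZ <- dA * (fw$A[[l]] > 0)
    }
  }
  list(loss = lo$loss, grads = grads, p = lo$p)
}

# --- 1-D CNN --------------------------------------------------------------

# im2col over the time axis: X [b, C, T] -> [b*T_out, C*k]
im2col <- function(X, k) {
  d <- dim(X); b <- d[1]; C <- d[2]; T_in <- d[3]
  T_out <- T_in - k + 1
  out <- matrix(0, b * T_out, C * k)
  for (dk in seq_len(k)) {
    sl <- X[, , dk:(dk + T_out - 1), drop = FALSE]       # [b, C, T_out]
    out[, ((dk - 1) * C + 1):(dk * C)] <-
      matrix(aperm(sl, c(1, 3, 2)), b * T_out, C)        # rows: (b, t)
  }
  out
}

col2im <- function(dcol, b, C, T_in, k) {
  T_out <- T_in - k + 1
  dX <- array(0, c(b, C, T_in))
  for (dk in seq_len(k)) {
    blk <- array(dcol[, ((dk - 1) * C + 1):(dk * C)], c(b, T_out, C))
    dX[, , dk:(dk + T_out - 1)] <- dX[, , dk:(dk + T_out - 1), drop = FALSE] +
      aperm(blk, c(1, 3, 2))
  }
  dX
}

cnn_init <- function(C, T_in, filters = c(32L, 64L), kernel = 3L) {
  T1 <- T_in - kernel + 1; T2 <- T1 - kernel + 1
  stopifnot(T2 >= 1)
  list(Wc1 = glorot(C * kernel, filters[1]),
       bc1 = matrix(0, 1, filters[1]),
       Wc2 = glorot(filters[1] * kernel, filters[2]),
       bc2 = matrix(0, 1, filters[2]),
       Wd = glorot(filters[2], 1),
       bd = matrix(0, 1, 1))
}

cnn_forward <- function(params, X, kernel = 3L) {
  d <- dim(X); b <- d[1]; C <- d[2]; T_in <- d[3]
  F1 <- ncol(params$Wc1); F2 <- ncol(params$Wc2)
  T1 <- T_in - kernel + 1; T2 <- T1 - kernel + 1
  X1col <- im2col(X, kernel)
  Z1 <- X1col %*% params$Wc1 +
    matrix(params$bc1, nrow(X1col), F1, byrow = TRUE)
  A1 <- relu(Z1)                                   # [b*T1, F1], rows (b, t)
  A1arr <- aperm(array(A1, c(b, T1, F1)), c(1, 3, 2))  # [b, F1, T1]
  X2col <- im2col(A1arr, kernel)
  Z2 <- X2col %*% params$Wc2 +
    matrix(params$bc2, nrow(X2col), F2, byrow = TRUE)
  A2 <- relu(Z2)                                   # [b*T2, F2]
  A2arr <- array(A2, c(b, T2, F2))
  pooled <- apply(A2arr, c(1, 3), mean)            # [b, F2] global average
  z <- pooled %*% params$Wd +
    matrix(params$bd, b, 1, byrow = TRUE)
  list(z = z[, 1], X1col = X1col, Z1 = Z1, A1arr = A1arr, X2col = X2col,
       Z2 = Z2, pooled = pooled, dims = list(b = b, C = C, T_in = T_in,
                                             T1 = T1, T2 = T2, F1 = F1,
                                             F2 = F2))
}

cnn_fwd_bwd <- function(params, X, y, kernel = 3L) {
  fw <- cnn_forward(params, X, kernel)
  lo <- bce_logits(fw$z, y)
  dm <- fw$dims
  grads <- params
  dzc <- matrix(lo$dz, ncol = 1)
  grads$Wd <- crossprod(fw$pooled, dzc)
  grads$bd <- matrix(sum(dzc), 1, 1)
  dpooled <- dzc %*% t(params$Wd)                  # [b, F2]
  # undo global average pool: each (b, t, f) gets dpooled[b, f] / T2
  dA2 <- array(0, c(dm$b, dm$T2, dm$F2))
  for (f in seq_len(dm$F2)) dA2[, , f] <- dpooled[, f] / dm$T2
  dZ2 <- matrix(dA2, dm$b * dm$T2, dm$F2) * (fw$Z2 > 0)
  grads$Wc2 <- crossprod(fw$X2col, dZ2)
  grads$bc2 <- matrix(colSums(dZ2), 1)
  dX2col <- dZ2 %*% t(params$Wc2)
  dA1arr <- col2im(dX2col, dm$b, dm$F1, dm$T1, kernel)   # [b, F1, T1]
  dA1 <- matrix(aperm(dA1arr, c(1, 3, 2)), dm$b * dm$T1, dm$F1)
  dZ1 <- dA1 * (fw$Z1 > 0)
  grads$Wc1 <- crossprod(fw$X1col, dZ1)
  grads$bc1 <- matrix(colSums(dZ1), 1)
  list(loss = lo$loss, grads = grads, p = lo$p)
}

# --- LSTM / BLSTM ---------------------------------------------------------

lstm_cell_init <- function(C, H, prefix) {
  out <- list()
  out[[paste0(prefix, "Wx")]] <- glorot(C, 4 * H)
  out[[paste0(prefix, "Wh")]] <- glorot(H, 4 * H)
  bb <- matrix(0, 1, 4 * H)
  bb[1, (H + 1):(2 * H)] <- 1   # forget-gate bias init
  out[[paste0(prefix, "b")]] <- bb
  out
}

# Runs one direction over X [b, C, T]; returns final hidden state and the
# caches needed for BPTT. Gate order: input, forget, cell, output.
lstm_forward_dir <- function(Wx, Wh, b, X, reverse = FALSE) {
  d <- dim(X); bs <- d[1]; T_in <- d[3]; H <- ncol(Wh) / 4
  steps <- if (reverse) rev(seq_len(T_in)) else seq_len(T_in)
  h <- matrix(0, bs, H); cc <- matrix(0, bs, H)
  cache <- vector("list", T_in)
  for (si in seq_along(steps)) {
    Xt <- matrix(X[, , steps[si]], bs)
    G <- Xt %*% Wx + h %*% Wh + matrix(b, bs, 4 * H, byrow = TRUE)
    i_g <- 1 / (1 + exp(-G[, 1:H, drop = FALSE]))
    f_g <- 1 / (1 + exp(-G[, (H + 1):(2 * H), drop = FALSE]))
    g_g <- tanh(G[, (2 * H + 1):(3 * H), drop = FALSE])
    o_g <- 1 / (1 + exp(-G[, (3 * H + 1):(4 * H), drop = FALSE]))
    c_new <- f_g * cc + i_g * g_g
    h_new <- o_g * tanh(c_new)
    cache[[si]] <- list(Xt = Xt, h_prev = h, c_prev = cc, i = i_g, f = f_g,
                        g = g_g, o = o_g, c_new = c_new)
    h <- h_new; cc <- c_new
  }
  list(h = h, cache = cache, steps = steps, H = H, bs = bs)
}

# BPTT for one direction given dL/dh_final; returns grads for Wx, Wh, b.
lstm_backward_dir <- function(Wx, Wh, b, fw, dh_final) {
  H <- fw$H; bs <- fw$bs
  dWx <- Wx * 0; dWh <- Wh * 0; db <- b * 0
  dh <- dh_final; dc <- matrix(0, bs, H)
  for (si in rev(seq_along(fw$cache))) {
    ca <- fw$cache[[si]]
    tc <- tanh(ca$c_new)
    do_ <- dh * tc
    dc <- dc + dh * ca$o * (1 - tc^2)
    di <- dc * ca$g
    df <- dc * ca$c_prev
    dg <- dc * ca$i
    dGi <- di * ca$i * (1 - ca$i)
    dGf <- df * ca$f * (1 - ca$f)
    dGg <- dg * (1 - ca$g^2)
    dGo <- do_ * ca$o * (1 - ca$o)
    dG <- cbind(dGi, dGf, dGg, dGo)
    dWx <- dWx + crossprod(ca$Xt, dG)
    dWh <- dWh + crossprod(ca$h_prev, dG)
    db <- db + matrix(colSums(dG), 1)
    dh <- dG %*% t(Wh)
    dc <- dc * ca$f
  }
  list(dWx = dWx, dWh = dWh, db = db)
}

lstm_init <- function(C, H, bidirectional = FALSE, head = integer(0)) {
  params <- lstm_cell_init(C, H, "f_")
  if (bidirectional) params <- c(params, lstm_cell_init(C, H, "r_"))
  d_in <- if (bidirectional) 2 * H else H
  sizes <- c(d_in, head, 1L)
  for (l in seq_len(length(sizes) - 1)) {
    params[[paste0("Wd", l)]] <- glorot(sizes[l], sizes[l + 1])
    params[[paste0("bd", l)]] <- matrix(0, 1, sizes[l + 1])
  }
  params
}

lstm_forward <- function(params, X, bidirectional = FALSE) {
  fwd <- lstm_forward_dir(params$f_Wx, params$f_Wh, params$f_b, X)
  feat <- fwd$h
  rwd <- NULL
  if (bidirectional) {
    rwd <- lstm_forward_dir(params$r_Wx, params$r_Wh, params$r_b, X,
                            reverse = TRUE)
    feat <- cbind(feat, rwd$h)
  }
  nl <- sum(grepl("^Wd", names(params)))
  A <- list(feat)
  for (l in seq_len(nl)) {
    Z <- A[[l]] %*% params[[paste0("Wd", l)]] +
      matrix(params[[paste0("bd", l)]], nrow(feat),
             ncol(params[[paste0("Wd", l)]]), byrow = TRUE)
    A[[l + 1]] <- if (l < nl) relu(Z) else Z
  }
  list(z = A[[nl + 1]][, 1], fwd = fwd, rwd = rwd, A = A, nl = nl)
}

lstm_fwd_bwd <- function(params, X, y, bidirectional = FALSE) {
  fw <- lstm_forward(params, X, bidirectional)
  lo <- bce_logits(fw$z, y)
  grads <- params
  dZ <- matrix(lo$dz, ncol = 1)
  for (l in fw$nl:1) {
    grads[[paste0("Wd", l)]] <- crossprod(fw$A[[l]], dZ)
    grads[[paste0("bd", l)]] <- matrix(colSums(dZ), 1)
    dA <- dZ %*% t(params[[paste0("Wd", l)]])
    if (l > 1) dZ <- dA * (fw$A[[l]] > 0)
    else dfeat <- dA
  }
  H <- fw$fwd$H
  gf <- lstm_backward_dir(params$f_Wx, params$f_Wh, params$f_b, fw$fwd,
                          dfeat[, seq_len(H), drop = FALSE])
  grads$f_Wx <- gf$dWx; grads$f_Wh <- gf$dWh; grads$f_b <- gf$db
  if (bidirectional) {
    gr <- lstm_backward_dir(params$r_Wx, params$r_Wh, params$r_b, fw$rwd,
                            dfeat[, (H + 1):(2 * H), drop = FALSE])
    grads$r_Wx <- gr$dWx; grads$r_Wh <- gr$dWh; grads$r_b <- gr$db
  }
  list(loss = lo$loss, grads = grads, p = lo$p)
}

# --- Adam + training loop -------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, st, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (k in names(params)) {
    st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * grads[[k]]
    st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * grads[[k]]^2
    mhat <- st$m[[k]] / (1 - b1^st$t)
    vhat <- st$v[[k]] / (1 - b2^st$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

# Family-generic batch closures.
nn_family_ops <- function(family, spec) {
  switch(family,
    mlp = list(
      init = function(dims) mlp_init(dims$d, spec$hidden),
      fwd_bwd = function(p, Xb, yb) mlp_fwd_bwd(p, Xb, yb),
      predict = function(p, Xb) {
        1 / (1 + exp(-mlp_forward(p, Xb)$z))
      }),
    cnn1d = list(
      init = function(dims) cnn_init(dims$C, dims$T, spec$filters,
                                     spec$kernel),
      fwd_bwd = function(p, Xb, yb) cnn_fwd_bwd(p, Xb, yb, spec$kernel),
      predict = function(p, Xb) {
        1 / (1 + exp(-cnn_forward(p, Xb, spec$kernel)$z))
      }),
    lstm = ,
    blstm = list(
      init = function(dims) lstm_init(dims$C, spec$hidden_lstm,
                                      family == "blstm", spec$head),
      fwd_bwd = function(p, Xb, yb) lstm_fwd_bwd(p, Xb, yb,
                                                 family == "blstm"),
      predict = function(p, Xb) {
        1 / (1 + exp(-lstm_forward(p, Xb, family == "blstm")$z))
      })
  )
}

slice_batch <- function(X, idx) {
  if (is.matrix(X)) X[idx, , drop = FALSE]
  else X[idx, , , drop = FALSE]
}

# Train a neural family with Adam, minibatches and (when a validation set
# is given) early stopping on validation loss with the configured patience.
nn_train <- function(family, spec, X, y, X_val = NULL, y_val = NULL,
                     seed = 1L) {
  ops <- nn_family_ops(family, spec)
  dims <- if (is.matrix(X)) list(d = ncol(X)) else {
    list(C = dim(X)[2], T = dim(X)[3])
  }
  with_seed(seed, {
    params <- ops$init(dims)
    st <- adam_new(params)
    n <- if (is.matrix(X)) nrow(X) else dim(X)[1]
    best_params <- params; best_val <- Inf; wait <- 0
    for (epoch in seq_len(spec$max_epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1, n, by = spec$batch_size)) {
        idx <- ord[b0:min(b0 + spec$batch_size - 1, n)]
        fb <- ops$fwd_bwd(params, slice_batch(X, idx), y[idx])
        upd <- adam_step(params, fb$grads, st, lr = spec$learning_rate,
                         b1 = spec$beta1, b2 = spec$beta2)
        params <- upd$params; st <- upd$state
      }
      if (!is.null(X_val)) {
        pv <- ops$predict(params, X_val)
        pv <- pmin(pmax(pv, 1e-12), 1 - 1e-12)
        val_loss <- -mean(y_val * log(pv) + (1 - y_val) * log(1 - pv))
        if (val_loss < best_val - 1e-6) {
          best_val <- val_loss; best_params <- params; wait <- 0
        } else {
          wait <- wait + 1
          if (wait >= spec$patience) break
        }
      } else {
        best_params <- params
      }
    }
    list(params = best_params, predict = ops$predict)
  })
}
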