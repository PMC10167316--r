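# Shared fixture builders and independent oracles.

# Epochs holding arbitrary data: trials x channels x time.
make_epochs <- function(data, fs = 512, tmin_s = 0,
                        roles = rep("scalp", dim(data)[2]),
                        names = sprintf("ch%02d", seq_len(dim(data)[2])),
                        group = "high", subject = "s01") {
  vulneeg:::new_epochs(data, tmin_s, fs, names, roles,
                       events = data.frame(onset_s = rep(0, dim(data)[1])),
                       subject_id = subject, group = group)
}

# Epochs on the full 34-channel montage layout (scalp names + 2 EOG).
make_montage_epochs <- function(n_trials, n_time, fs = 512, fill = 0,
                                group = "high", subject = "s01") {
  mont <- build_montage()
  nm <- c(mont$channel_names, "EOG1", "EOG2")
  data <- array(fill, c(n_trials, length(nm), n_time))
  make_epochs(data, fs = fs, roles = c(rep("scalp", 32), "eog", "eog"),
              names = nm, group = group, subject = subject)
}

# Sinusoid helper.
sine_wave <- function(freq, fs, n, phase = 0, amp = 1) {
  amp * sin(2 * pi * freq * (seq_len(n) - 1) / fs + phase)
}

# A feature table built directly from a matrix (bypasses EEG extraction).
make_feature_table <- function(X, group, measure = "band_power",
                               band = "delta",
                               location = sprintf("ch%02d", seq_len(ncol(X)))) {
  cn <- sprintf("%s|%s|%s", measure, band, location)
  colnames(X) <- cn
  ft <- data.frame(subject_id = sprintf("s%03d", seq_len(nrow(X))),
                   group = group, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ft <- cbind(ft, as.data.frame(X, check.names = FALSE))
  attr(ft, "descriptors") <- vulneeg:::parse_descriptors(cn)
  class(ft) <- c("feature_table", "data.frame")
  ft
}

# Sample with exactly the requested mean and SD.
exact_sample <- function(n, mean, sd, seed = 1) {
  x <- withr::with_seed(seed, stats::rnorm(n))
  as.vector(scale(x)) * sd + mean
}

# Independent Benjamini-Hochberg step-up oracle (brute force from the
# definition: largest i with p_(i) <= i*q/m).
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0) return(rep(FALSE, m))
  thr <- ps[max(ok)]
  p <= thr
}

# Central finite-difference gradient of a scalar loss over a param list.
numeric_gradient <- function(loss_fn, params, eps = 1e-5) {
  g <- params
  for (k in names(params)) {
    gk <- params[[k]] * 0
    for (i in seq_along(params[[k]])) {
      p1 <- params; p1[[k]][i] <- p1[[k]][i] + eps
      p2 <- params; p2[[k]][i] <- p2[[k]][i] - eps
      gk[i] <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
    }
    g[[k]] <- gk
  }
  g
}

max_grad_err <- function(analytic, numeric) {
  max(mapply(function(a, b) max(abs(a - b)), analytic, numeric))
}

# Windowed dataset built directly from arrays.
make_windowed <- function(X, y, subject_id) {
  structure(list(X = X, y = y, subject_id = subject_id,
                 window = dim(X)[3], stride = dim(X)[3]),
            class = "windowed_dataset")
}

# 99% binomial interval for a count.
binom99 <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p)
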