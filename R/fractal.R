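# Nonlinear single-channel complexity measures.

#' Higuchi fractal dimension
#'
#' Curve-length method: for each scale k = 1..kmax and offset m, the
#' normalized length of the subsampled curve x(m), x(m+k), ... is computed;
#' lengths are averaged over offsets and the dimension is the slope of
#' log L(k) against log(1/k). Smooth trends give D near 1, white noise
#' near 2. Invariant to affine transforms of the signal.
#'
#' @param x numeric vector (length >= 10*kmax), non-constant.
#' @param kmax maximum scale (default 8).
#' @return The fractal dimension estimate.
#' @export
higuchi_fd <- function(x, kmax = 8L) {
  n <- length(x)
  assert_scalar_num(kmax, "kmax", 2)
  kmax <- as.integer(kmax)
  if (n < 10 * kmax) stop_invalid("signal too short for kmax = %d", kmax)
  if (stats::sd(x) == 0) stop_invalid("constant signal has no curve length")
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      ni <- length(idx) - 1L
      if (ni < 1) { lm[m] <- NA; next }
      lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (ni * k) / k
    }
    lk[k] <- mean(lm, na.rm = TRUE)
  }
  if (any(lk <= 0)) stop_invalid("degenerate curve length")
  stats::coef(stats::lm(log(lk) ~ log(1 / seq_len(kmax))))[[2]]
}

#' Detrended fluctuation analysis exponent
#'
#' Integrates the mean-removed signal into a profile, splits the profile
#' into non-overlapping windows per scale, removes a per-window linear
#' trend, and regresses the log RMS fluctuation on log scale. White noise
#' gives alpha near 0.5, 1/f noise near 1, a random walk near 1.5.
#' Invariant to affine transforms of the signal.
#'
#' @param x numeric vector, non-constant.
#' @param scales integer window sizes (>= 4 distinct values); default
#'   log-spaced between 4 and length(x)/4.
#' @return The scaling exponent alpha.
#' @export
dfa_exponent <- function(x, scales = NULL) {
  n <- length(x)
  if (stats::sd(x) == 0) stop_invalid("constant signal")
  if (is.null(scales)) {
    scales <- unique(round(exp(seq(log(4), log(n / 4), length.out = 12))))
  }
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 4) stop_invalid("need at least 4 scales")
  if (max(scales) * 4 > n) stop_invalid("signal too short for max scale %d",
                                        max(scales))
  y <- cumsum(x - mean(x))
  fs_ <- numeric(length(scales))
  for (si in seq_along(scales)) {
    s <- scales[si]
    n_win <- floor(n / s)
    segs <- matrix(y[seq_len(n_win * s)], nrow = s)   # one window per column
    X <- cbind(1, seq_len(s))
    resid <- segs - X %*% solve(crossprod(X), crossprod(X, segs))
    fs_[si] <- sqrt(mean(resid^2))
  }
  stats::coef(stats::lm(log(fs_) ~ log(scales)))[[2]]
}
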