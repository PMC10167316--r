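# Channel-pair connectivity measures. All return symmetric channel x channel
# matrices restricted to scalp channels, wrapped with measure/band metadata.

new_connectivity <- function(values, measure, band, channels) {
  dimnames(values) <- list(channels, channels)
  structure(
    list(values = values, measure = measure, band = band,
         channels = channels),
    class = "eeg_connectivity"
  )
}

#' @export
print.eeg_connectivity <- function(x, ...) {
  cat(sprintf("<eeg_connectivity> %s (%s), %d channels\n",
              x$measure, x$band, length(x$channels)))
  invisible(x)
}

scalp_epoch_matrix <- function(ep, trial) {
  scalp <- which(ep$channel_roles == "scalp")
  list(x = ep$data[trial, scalp, , drop = TRUE],
       channels = ep$channel_names[scalp])
}

#' Pearson correlation connectivity
#'
#' Band-filters the epochs, computes the channel-pair Pearson correlation
#' within each trial, and averages the coefficients across trials.
#'
#' @param ep an `eeg_epochs` (scalp channels used).
#' @param band band name or definition ("raw" = no further filtering).
#' @return An `eeg_connectivity` with `measure = "correlation"`.
#' @export
connectivity_correlation <- function(ep, band = "raw") {
  stopifnot(inherits(ep, "eeg_epochs"))
  ep <- band_filter(ep, band)
  d <- dim(ep$data)
  if (d[1] == 0) stop_invalid("no trials")
  acc <- NULL
  for (tr in seq_len(d[1])) {
    m <- scalp_epoch_matrix(ep, tr)
    sds <- apply(m$x, 1, stats::sd)
    if (any(sds == 0)) stop_invalid("zero-variance channel in trial %d", tr)
    r <- stats::cor(t(m$x))
    acc <- if (is.null(acc)) r else acc + r
  }
  m <- scalp_epoch_matrix(ep, 1)
  new_connectivity(acc / d[1], "correlation", as_band(band)$name, m$channels)
}

#' Spectral coherence connectivity
#'
#' Complex coherency per frequency bin — the Welch-averaged cross-spectrum
#' normalized by the auto-spectra, with segments pooled over windows and
#' trials — then averaged over the band's bins. Returns both the coherence
#' magnitude and the magnitude of the imaginary part. The raw imaginary
#' coherency is antisymmetric in the channel order (its sign encodes
#' lead/lag), so its absolute value is stored: the matrix then obeys the
#' symmetric-matrix contract while remaining insensitive to zero-lag
#' (volume-conducted) coupling.
#'
#' @param ep an `eeg_epochs`.
#' @param band band name or definition.
#' @param window_sec Welch window (default 2 s, capped at epoch length).
#' @return list with `coherence_mag` and `coherence_imag`
#'   (`eeg_connectivity`).
#' @export
connectivity_coherence <- function(ep, band = "raw", window_sec = 2) {
  stopifnot(inherits(ep, "eeg_epochs"))
  band <- as_band(band)
  d <- dim(ep$data)
  if (d[1] == 0) stop_invalid("no trials")
  scalp <- which(ep$channel_roles == "scalp")
  channels <- ep$channel_names[scalp]
  nc <- length(scalp)
  S <- NULL   # [bin, i, j] accumulated cross-spectra
  n_seg_total <- 0
  for (tr in seq_len(d[1])) {
    sf <- segment_ffts(ep$data[tr, scalp, , drop = TRUE], ep$fs, window_sec)
    bins <- band_bins(sf$freq, band)
    if (length(bins) == 0) stop_invalid("band contains no frequency bins")
    if (is.null(S)) S <- array(0i, c(length(bins), nc, nc))
    for (si in seq_len(dim(sf$ffts)[2])) {
      Z <- sf$ffts[bins, si, , drop = FALSE][, 1, ]  # bins x channels
      if (length(bins) == 1) Z <- matrix(Z, nrow = 1)
      for (bi in seq_along(bins)) {
        S[bi, , ] <- S[bi, , ] + outer(Z[bi, ], Conj(Z[bi, ]))
      }
      n_seg_total <- n_seg_total + 1
    }
  }
  if (n_seg_total < 2) stop_invalid("need at least 2 spectral windows")
  mag <- matrix(0, nc, nc); im <- matrix(0, nc, nc)
  for (bi in seq_len(dim(S)[1])) {
    auto <- Re(diag(S[bi, , ]))
    denom <- sqrt(auto %o% auto)
    C <- S[bi, , ] / denom
    mag <- mag + abs(C)
    im <- im + abs(Im(C))
  }
  nb <- dim(S)[1]
  list(
    coherence_mag = new_connectivity(mag / nb, "coherence_mag", band$name,
                                     channels),
    coherence_imag = new_connectivity(im / nb, "coherence_imag", band$name,
                                      channels)
  )
}

# Analytic signal via the FFT half-spectrum construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Phase-based connectivity: PLV and PLI
#'
#' Band-filters the epochs (a narrow band is required; "raw" is rejected),
#' extracts instantaneous phase from the analytic signal, discards 5% of
#' samples at each epoch edge to suppress filter transients, and pools phase
#' differences over time and trials. PLV is the modulus of the mean unit
#' phasor of the phase difference; PLI is the absolute mean sign of its
#' sine, which vanishes for zero-lag (volume-conducted) coupling.
#'
#' @param ep an `eeg_epochs`.
#' @param band a narrow band ("delta".."gamma"); "raw" is an error.
#' @return list with `plv` and `pli` (`eeg_connectivity`).
#' @export
connectivity_phase <- function(ep, band) {
  stopifnot(inherits(ep, "eeg_epochs"))
  band <- as_band(band)
  if (band$name == "raw") {
    stop_invalid("phase connectivity needs a narrow band, not 'raw'")
  }
  ep <- band_filter(ep, band)
  d <- dim(ep$data)
  if (d[1] == 0) stop_invalid("no trials")
  scalp <- which(ep$channel_roles == "scalp")
  channels <- ep$channel_names[scalp]
  nc <- length(scalp)
  n_t <- d[3]
  edge <- max(1L, round(0.05 * n_t))
  keep <- (edge + 1):(n_t - edge)
  # phase array [trials, channels, time]
  ph <- array(0, c(d[1], nc, length(keep)))
  for (tr in seq_len(d[1])) {
    for (k in seq_len(nc)) {
      a <- analytic_signal(ep$data[tr, scalp[k], ])
      ph[tr, k, ] <- Arg(a)[keep]
    }
  }
  plv <- diag(nc); pli <- matrix(0, nc, nc)
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      dphi <- ph[, i, ] - ph[, j, ]
      plv[i, j] <- plv[j, i] <- Mod(mean(exp(1i * dphi)))
      pli[i, j] <- pli[j, i] <- abs(mean(sign(sin(dphi))))
    }
  }
  list(
    plv = new_connectivity(plv, "plv", band$name, channels),
    pli = new_connectivity(pli, "pli", band$name, channels)
  )
}
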