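# Welch spectral estimation. Hann windows with 50% overlap, per-segment mean
# removal, one-sided density scaling. The default 2 s window gives 0.5 Hz
# resolution, enough to resolve the delta band; windows are capped at the
# signal length so short epochs degrade to a single segment.

welch_segments <- function(n, win_len, overlap) {
  step <- max(1L, round(win_len * (1 - overlap)))
  starts <- seq(1L, n - win_len + 1L, by = step)
  starts
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

# FFTs of windowed, demeaned segments for a channels x samples matrix.
# Returns list(freq, ffts = array [n_freq, n_seg, n_chan], scale) where
# sum over bins of scale*|fft|^2*df approximates signal variance.
segment_ffts <- function(x, fs, window_sec = 2, overlap = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  n <- ncol(x)
  win_len <- min(n, round(window_sec * fs))
  if (win_len < 8) stop_invalid("signal too short for spectral estimation")
  starts <- welch_segments(n, win_len, overlap)
  w <- hann_window(win_len)
  n_freq <- floor(win_len / 2) + 1L
  out <- array(0i, c(n_freq, length(starts), nrow(x)))
  for (ci in seq_len(nrow(x))) {
    for (si in seq_along(starts)) {
      seg <- x[ci, starts[si]:(starts[si] + win_len - 1L)]
      seg <- (seg - mean(seg)) * w
      out[, si, ci] <- stats::fft(seg)[seq_len(n_freq)]
    }
  }
  freq <- (seq_len(n_freq) - 1L) * fs / win_len
  # one-sided PSD scale (doubling interior bins)
  scale <- rep(2 / (fs * sum(w^2)), n_freq)
  scale[1] <- scale[1] / 2
  if (win_len %% 2 == 0) scale[n_freq] <- scale[n_freq] / 2
  list(freq = freq, ffts = out, scale = scale, win_len = win_len)
}

# Welch PSD for one channels x samples matrix -> n_freq x n_chan matrix.
welch_psd <- function(x, fs, window_sec = 2, overlap = 0.5) {
  sf <- segment_ffts(x, fs, window_sec, overlap)
  # average |FFT|^2 over segments (dim 2) without apply() overhead
  p <- colMeans(aperm(abs(sf$ffts)^2, c(2, 1, 3))) * sf$scale
  list(freq = sf$freq, psd = p, df = sf$freq[2] - sf$freq[1])
}

band_bins <- function(freq, band) {
  band <- as_band(band)
  which(freq >= band$low_hz & freq < band$high_hz)
}

#' Band-pass filter epochs
#'
#' Zero-phase 4th-order Butterworth per trial and channel. Band "raw"
#' (0.5-40 Hz, the range already imposed by preprocessing) returns the
#' input unchanged.
#'
#' @param ep an `eeg_epochs`.
#' @param band band name or [band_definition()].
#' @return A filtered `eeg_epochs`.
#' @export
band_filter <- function(ep, band) {
  stopifnot(inherits(ep, "eeg_epochs"))
  band <- as_band(band)
  if (band$name == "raw") return(ep)
  check_band_edges(band$low_hz, band$high_hz, ep$fs)
  filt <- butter_bandpass(band$low_hz, band$high_hz, ep$fs)
  out <- ep
  d <- dim(ep$data)
  for (tr in seq_len(d[1])) {
    for (ci in seq_len(d[2])) {
      out$data[tr, ci, ] <- signal::filtfilt(filt, ep$data[tr, ci, ])
    }
  }
  out
}

#' Band power per channel
#'
#' Welch power spectral density integrated over `[low, high)` and averaged
#' across trials.
#'
#' @param ep an `eeg_epochs`.
#' @param band band name or definition.
#' @param window_sec Welch window length in seconds (default 2, capped at
#'   the epoch length).
#' @return Named numeric vector, one value per channel (uV^2).
#' @export
band_power <- function(ep, band, window_sec = 2) {
  stopifnot(inherits(ep, "eeg_epochs"))
  band <- as_band(band)
  d <- dim(ep$data)
  if (d[1] == 0) stop_invalid("no trials")
  acc <- matrix(0, nrow = d[2], ncol = 1)
  for (tr in seq_len(d[1])) {
    w <- welch_psd(ep$data[tr, , , drop = TRUE], ep$fs, window_sec)
    bins <- band_bins(w$freq, band)
    if (length(bins) == 0) stop_invalid("band contains no frequency bins")
    acc <- acc + colSums(w$psd[bins, , drop = FALSE]) * w$df
  }
  p <- as.vector(acc) / d[1]
  names(p) <- ep$channel_names
  p
}

#' Relative band power per channel
#'
#' Band power divided by total 0.5-40 Hz power; values in [0, 1].
#'
#' @inheritParams band_power
#' @return Named numeric vector per channel.
#' @export
relative_band_power <- function(ep, band, window_sec = 2) {
  p <- band_power(ep, band, window_sec)
  tot <- band_power(ep, "raw", window_sec)
  if (any(tot <= 0)) stop_invalid("zero total power in some channel")
  p / tot
}

#' Frontal alpha asymmetry
#'
#' `ln(alpha power at right) - ln(alpha power at left)`; defaults to the
#' F4/F3 pair.
#'
#' @param ep an `eeg_epochs`.
#' @param left,right channel names (defaults "F3", "F4").
#' @return A single number.
#' @export
alpha_asymmetry <- function(ep, left = "F3", right = "F4") {
  p <- band_power(ep, "alpha")
  if (!left %in% names(p) || !right %in% names(p)) {
    stop_invalid("channels %s/%s not present", left, right)
  }
  if (p[left] <= 0 || p[right] <= 0) stop_invalid("nonpositive alpha power")
  unname(log(p[right]) - log(p[left]))
}
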