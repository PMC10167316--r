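# Zero-phase Butterworth filtering. All band-pass operations in the package
# go through a 4th-order Butterworth design applied forward-backward
# (signal::filtfilt), so the effective amplitude response is |H(f)|^2 and the
# phase response is zero. Narrow low-frequency bands (delta at fs = 512) stay
# numerically stable at this order.

butter_bandpass <- function(low_hz, high_hz, fs, order = 4L) {
  signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
}

# Apply a filter forward-backward along the rows of a channels x samples
# matrix.
filtfilt_rows <- function(filt, x) {
  out <- x
  for (i in seq_len(nrow(x))) {
    out[i, ] <- signal::filtfilt(filt, x[i, ])
  }
  out
}

check_band_edges <- function(low_hz, high_hz, fs) {
  assert_scalar_num(low_hz, "low_hz")
  assert_scalar_num(high_hz, "high_hz")
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2)) {
    stop_invalid("band edges must satisfy 0 < low (%g) < high (%g) < fs/2 (%g)",
                 low_hz, high_hz, fs / 2)
  }
}

#' Band-pass filter a continuous recording
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass applied to
#' every channel, EOG included. Signal length is preserved.
#'
#' @param rec an `eeg_recording`.
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low < high < fs/2`. Defaults 0.5-40 Hz.
#' @return A new filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low_hz = 0.5, high_hz = 40) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_band_edges(low_hz, high_hz, rec$fs)
  filt <- butter_bandpass(low_hz, high_hz, rec$fs)
  out <- rec
  out$data <- filtfilt_rows(filt, rec$data)
  out
}

# Standard EEG frequency bands --------------------------------------------

#' Frequency band definitions
#'
#' The conventional bands tiling the 0.5-40 Hz analysis range: delta 0.5-4,
#' theta 4-8, alpha 8-13, beta 13-30, gamma 30-40 Hz. "raw" denotes the full
#' 0.5-40 Hz range and triggers no further filtering.
#'
#' @param name one of "raw", "delta", "theta", "alpha", "beta", "gamma".
#' @return A list with `name`, `low_hz`, `high_hz`.
#' @export
band_definition <- function(name) {
  edges <- list(
    raw = c(0.5, 40), delta = c(0.5, 4), theta = c(4, 8),
    alpha = c(8, 13), beta = c(13, 30), gamma = c(30, 40)
  )
  if (!name %in% names(edges)) {
    stop_invalid("unknown band '%s' (expected one of %s)",
                 name, paste(names(edges), collapse = ", "))
  }
  e <- edges[[name]]
  list(name = name, low_hz = e[1], high_hz = e[2])
}

#' @rdname band_definition
#' @export
band_names <- function() c("raw", "delta", "theta", "alpha", "beta", "gamma")

as_band <- function(band) {
  if (is.character(band)) band_definition(band) else band
}
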