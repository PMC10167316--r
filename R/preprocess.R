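# Epoch container and the deterministic preprocessing chain:
# filter -> segment -> baseline -> reject -> interpolate -> re-reference
# -> trim. All operations are pure (inputs untouched, new objects out).

new_epochs <- function(data, tmin_s, fs, channel_names, channel_roles,
                       events, subject_id = NA_character_,
                       group = NA_character_) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(channel_names))
  structure(
    list(data = data, tmin_s = tmin_s, fs = fs,
         channel_names = channel_names, channel_roles = channel_roles,
         events = events, subject_id = subject_id, group = group),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d ch x %d samples @ %g Hz, tmin %g s\n",
              d[1], d[2], d[3], x$fs, x$tmin_s))
  invisible(x)
}

#' Epoch time axis
#' @param ep an `eeg_epochs`.
#' @return Vector of sample times in seconds relative to stimulus onset.
#' @export
epoch_times <- function(ep) {
  ep$tmin_s + (seq_len(dim(ep$data)[3]) - 1) / ep$fs
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' Sample convention: the epoch covers the half-open sample interval
#' `[onset_sample + round(tmin*fs), onset_sample + round(tmax*fs))` so an
#' epoch from -0.5 to 1.3 s at 512 Hz is exactly 922 samples. Events whose
#' window falls outside the recording are dropped and counted in the
#' `n_dropped` attribute.
#'
#' @param rec an `eeg_recording`.
#' @param events event table with an `onset_s` column.
#' @param tmin_s,tmax_s epoch window in seconds relative to onset
#'   (defaults -0.5 and 1.3).
#' @return An `eeg_epochs`; its `events` field holds the retained rows.
#' @export
segment_epochs <- function(rec, events, tmin_s = -0.5, tmax_s = 1.3) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (tmin_s >= tmax_s) stop_invalid("tmin_s must be < tmax_s")
  n_len <- round((tmax_s - tmin_s) * rec$fs)
  n_samp <- ncol(rec$data)
  if (nrow(events) == 0) {
    out <- new_epochs(array(0, c(0, nrow(rec$data), n_len)), tmin_s, rec$fs,
                      rec$channel_names, rec$channel_roles, events,
                      rec$subject_id, rec$group)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  onset_sample <- round(events$onset_s * rec$fs)  # 0-based sample of onset
  start0 <- onset_sample + round(tmin_s * rec$fs)
  ok <- start0 >= 0 & (start0 + n_len) <= n_samp
  kept <- which(ok)
  data <- array(0, c(length(kept), nrow(rec$data), n_len))
  for (j in seq_along(kept)) {
    s <- start0[kept[j]]
    data[j, , ] <- rec$data[, (s + 1):(s + n_len)]
  }
  out <- new_epochs(data, tmin_s, rec$fs, rec$channel_names,
                    rec$channel_roles, events[kept, , drop = FALSE],
                    rec$subject_id, rec$group)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (default the whole pre-stimulus interval).
#'
#' @param ep an `eeg_epochs`.
#' @param window `c(t0, t1)` in seconds, within `[tmin, 0]`; NULL uses
#'   `c(tmin, 0)`.
#' @return A corrected `eeg_epochs`.
#' @export
baseline_correct <- function(ep, window = NULL) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (is.null(window)) window <- c(ep$tmin_s, 0)
  tt <- epoch_times(ep)
  if (window[1] < ep$tmin_s - 1e-9 || window[2] > 1e-9 ||
      window[1] >= window[2]) {
    stop_invalid("baseline window must lie within [tmin, 0]")
  }
  sel <- tt >= window[1] - 1e-9 & tt < window[2] - 1e-9
  if (!any(sel)) stop_invalid("baseline window contains no samples")
  out <- ep
  bl <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
  out$data <- ep$data - as.vector(bl)  # recycles over 3rd dim
  out
}

#' Crop the epoch time window
#'
#' @param ep an `eeg_epochs`.
#' @param tmin_s,tmax_s requested window, nested inside the existing one
#'   (defaults -0.2 and 1.3).
#' @return A trimmed `eeg_epochs`; metadata preserved.
#' @export
trim_epochs <- function(ep, tmin_s = -0.2, tmax_s = 1.3) {
  stopifnot(inherits(ep, "eeg_epochs"))
  old_len <- dim(ep$data)[3]
  old_tmax <- ep$tmin_s + old_len / ep$fs
  if (tmin_s < ep$tmin_s - 1e-9 || tmax_s > old_tmax + 1e-9 ||
      tmin_s >= tmax_s) {
    stop_invalid("requested window [%g, %g] not nested in [%g, %g]",
                 tmin_s, tmax_s, ep$tmin_s, old_tmax)
  }
  start <- round((tmin_s - ep$tmin_s) * ep$fs)
  len <- round((tmax_s - tmin_s) * ep$fs)
  out <- ep
  out$data <- ep$data[, , (start + 1):(start + len), drop = FALSE]
  out$tmin_s <- ep$tmin_s + start / ep$fs
  out
}

#' Reject high-amplitude trials
#'
#' A trial is rejected when any scalp channel's peak-to-peak amplitude
#' within the epoch exceeds the threshold — an automatic stand-in for
#' visual artifact marking (drifts, movement, blinks).
#'
#' @param ep an `eeg_epochs`.
#' @param ptp_threshold_uv peak-to-peak threshold in microvolts
#'   (default 150).
#' @return list with `epochs` (kept trials) and `report`
#'   (`n_total`, `n_rejected`, `proportion_rejected`, per-trial `reason`).
#' @export
reject_artifacts <- function(ep, ptp_threshold_uv = 150) {
  stopifnot(inherits(ep, "eeg_epochs"))
  assert_scalar_num(ptp_threshold_uv, "ptp_threshold_uv", 1e-12)
  scalp <- which(ep$channel_roles == "scalp")
  n <- dim(ep$data)[1]
  bad <- logical(n)
  if (n > 0) {
    ptp <- apply(ep$data[, scalp, , drop = FALSE], c(1, 2),
                 function(x) max(x) - min(x))
    bad <- apply(ptp, 1, max) > ptp_threshold_uv
  }
  out <- ep
  out$data <- ep$data[!bad, , , drop = FALSE]
  out$events <- ep$events[!bad, , drop = FALSE]
  report <- list(
    n_total = n,
    n_rejected = sum(bad),
    proportion_rejected = if (n > 0) sum(bad) / n else 0,
    reason = ifelse(bad, "ptp_exceeded", "kept")
  )
  list(epochs = out, report = report)
}

#' Interpolate bad channels from montage neighbors
#'
#' Each bad channel is replaced, sample by sample, by the mean of its
#' non-bad montage neighbors.
#'
#' @param ep an `eeg_epochs`.
#' @param bad character vector of bad channel names (may be empty).
#' @param montage an `eeg_montage` supplying the neighbor sets.
#' @return An `eeg_epochs` with bad channels replaced.
#' @export
interpolate_bad_channels <- function(ep, bad, montage) {
  stopifnot(inherits(ep, "eeg_epochs"), inherits(montage, "eeg_montage"))
  if (length(bad) == 0) return(ep)
  montage_check_channels(montage, bad)
  miss <- setdiff(bad, ep$channel_names)
  if (length(miss)) stop_invalid("bad channel(s) not in epochs: %s",
                                 paste(miss, collapse = ", "))
  out <- ep
  for (ch in bad) {
    nb <- setdiff(montage$neighbors[[ch]], bad)
    if (length(nb) == 0) {
      stop_invalid("all neighbors of %s are themselves bad", ch)
    }
    i_ch <- match(ch, ep$channel_names)
    i_nb <- match(nb, ep$channel_names)
    repl <- apply(ep$data[, i_nb, , drop = FALSE], c(1, 3), mean)
    out$data[, i_ch, ] <- repl
  }
  out
}

#' Re-reference to the scalp average
#'
#' At every sample the mean over scalp (non-EOG) channels is subtracted from
#' each scalp channel; EOG channels are left untouched.
#'
#' @param ep an `eeg_epochs`.
#' @return A re-referenced `eeg_epochs`.
#' @export
rereference_average <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  scalp <- which(ep$channel_roles == "scalp")
  if (length(scalp) < 2) stop_invalid("need at least 2 scalp channels")
  out <- ep
  avg <- apply(ep$data[, scalp, , drop = FALSE], c(1, 3), mean)
  for (i in scalp) out$data[, i, ] <- ep$data[, i, ] - avg
  out
}

#' Run the default preprocessing chain
#'
#' Band-pass filter (0.5-40 Hz), segment (-0.5..1.3 s), baseline-correct on
#' the pre-stimulus interval, reject trials by peak-to-peak threshold,
#' interpolate any listed bad channels, re-reference to the scalp average,
#' and trim to the analysis window (-0.2..1.3 s).
#'
#' @param rec an `eeg_recording`.
#' @param events event table.
#' @param low_hz,high_hz filter band (defaults 0.5, 40).
#' @param tmin_s,tmax_s segmentation window (defaults -0.5, 1.3).
#' @param trim_to analysis window after trimming (default `c(-0.2, 1.3)`).
#' @param ptp_threshold_uv rejection threshold (default 150).
#' @param bad_channels channels to interpolate (default none).
#' @param montage montage for interpolation (default [build_montage()]).
#' @return list with `epochs` and the rejection `report`.
#' @export
preprocess_recording <- function(rec, events, low_hz = 0.5, high_hz = 40,
                                 tmin_s = -0.5, tmax_s = 1.3,
                                 trim_to = c(-0.2, 1.3),
                                 ptp_threshold_uv = 150,
                                 bad_channels = character(),
                                 montage = build_montage()) {
  rec <- bandpass_filter(rec, low_hz, high_hz)
  ep <- segment_epochs(rec, events, tmin_s, tmax_s)
  ep <- baseline_correct(ep)
  rej <- reject_artifacts(ep, ptp_threshold_uv)
  ep <- interpolate_bad_channels(rej$epochs, bad_channels, montage)
  ep <- rereference_average(ep)
  ep <- trim_epochs(ep, trim_to[1], trim_to[2])
  list(epochs = ep, report = rej$report)
}

#' Cut a resting recording into fixed-length pseudo-epochs
#'
#' Resting data has no events; analyses use consecutive non-overlapping
#' windows as trials (no baseline/trim semantics; tmin = 0).
#'
#' @param rec an `eeg_recording`.
#' @param epoch_s window length in seconds (default 2).
#' @return An `eeg_epochs`.
#' @export
rest_epochs <- function(rec, epoch_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(epoch_s * rec$fs)
  n_ep <- floor(ncol(rec$data) / len)
  if (n_ep < 1) stop_invalid("recording shorter than one epoch")
  data <- array(0, c(n_ep, nrow(rec$data), len))
  for (j in seq_len(n_ep)) {
    data[j, , ] <- rec$data[, ((j - 1) * len + 1):(j * len)]
  }
  ev <- data.frame(onset_s = (seq_len(n_ep) - 1) * epoch_s)
  new_epochs(data, 0, rec$fs, rec$channel_names, rec$channel_roles, ev,
             rec$subject_id, rec$group)
}
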