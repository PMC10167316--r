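# Synthetic two-group EEG cohorts: 1/f background per channel, planted
# band-limited amplitude effects at named channels (high-vulnerability group
# only) and phase-lagged band-limited coupling at named channel pairs, plus
# EOG channels carrying blink transients that leak into frontal electrodes.

#' Specify planted group effects
#'
#' @param amplitude list of amplitude effects, each
#'   `list(channel=, band=, factor=)`: the named band's amplitude at that
#'   channel is multiplied by `factor` in the high-vulnerability group.
#' @param coupling list of coupling effects, each
#'   `list(pair=c(chA, chB), band=, phase_lag=, mix=, group="high")`: a
#'   shared band-limited noise carrier is added to both channels with a
#'   constant phase lag (radians, in (-pi, pi]) between them, at relative
#'   amplitude `mix` (0-1 of the background SD), for the stated group.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(amplitude = list(), coupling = list()) {
  for (a in amplitude) {
    stopifnot(all(c("channel", "band", "factor") %in% names(a)))
    if (a$factor <= 0) stop_invalid("amplitude factor must be > 0")
  }
  for (cp in coupling) {
    stopifnot(all(c("pair", "band", "phase_lag", "mix") %in% names(cp)))
    if (cp$mix < 0 || cp$mix > 1) stop_invalid("mix must be in [0, 1]")
    if (cp$phase_lag <= -pi || cp$phase_lag > pi) {
      stop_invalid("phase_lag must be in (-pi, pi]")
    }
  }
  structure(list(amplitude = amplitude, coupling = coupling),
            class = "effect_spec")
}

#' Specify a synthetic cohort
#'
#' Defaults mirror the study design: two groups of 20 subjects, 5-minute
#' resting recordings at 512 Hz on the 32-channel 10-20 montage.
#'
#' @param n_high,n_low subjects per group (>= 1).
#' @param rest_duration_s resting recording length in seconds (default 300).
#' @param fs sampling rate in Hz (default 512; must exceed twice the highest
#'   band edge, 40 Hz).
#' @param effect an [effect_spec()] of planted group differences.
#' @param noise_exponent 1/f spectral exponent of the background (default 1).
#' @param noise_sd_uv per-channel background standard deviation in microvolts.
#' @param blink_rate blink transients per second on the EOG channels
#'   (default 0.1); blinks leak into frontal scalp channels.
#' @param seed integer cohort seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_high = 20L, n_low = 20L, rest_duration_s = 300,
                        fs = 512, effect = effect_spec(),
                        noise_exponent = 1, noise_sd_uv = 10,
                        blink_rate = 0.1, seed = 1L) {
  assert_scalar_num(n_high, "n_high", 1)
  assert_scalar_num(n_low, "n_low", 1)
  assert_scalar_num(rest_duration_s, "rest_duration_s", 1)
  assert_scalar_num(fs, "fs", 80 + 1e-9)
  assert_scalar_num(noise_sd_uv, "noise_sd_uv", 0)
  assert_scalar_num(blink_rate, "blink_rate", 0)
  stopifnot(inherits(effect, "effect_spec"))
  structure(
    list(n_high = as.integer(n_high), n_low = as.integer(n_low),
         rest_duration_s = rest_duration_s, fs = fs, effect = effect,
         noise_exponent = noise_exponent, noise_sd_uv = noise_sd_uv,
         blink_rate = blink_rate, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

new_recording <- function(data, fs, channel_names, channel_roles,
                          subject_id, group) {
  stopifnot(nrow(data) == length(channel_names),
            length(channel_roles) == length(channel_names))
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         channel_roles = channel_roles, subject_id = subject_id,
         group = group),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s (%s): %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

scalp_idx <- function(rec) which(rec$channel_roles == "scalp")

# 1/f-shaped noise: white noise spectrally reweighted by |f|^(-exponent/2)
# (amplitude), DC removed. Scaling depends on |f| only, so conjugate
# symmetry - hence realness - is preserved.
one_over_f_noise <- function(n, fs, exponent, sd_target) {
  if (sd_target == 0) return(numeric(n))
  # work at a highly composite length (mixed-radix FFT stays O(m log m)
  # for any requested duration), then truncate
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  f <- c(0, seq_len(m - 1)) * fs / m
  f <- pmin(f, fs - f)  # two-sided |f|
  scale <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE))[seq_len(n)] / m
  x <- x - mean(x)
  x * sd_target / stats::sd(x)
}

# Band-limited unit-SD noise carrier.
band_carrier <- function(n, fs, band) {
  band <- as_band(band)
  x <- stats::rnorm(n)
  filt <- butter_bandpass(band$low_hz, band$high_hz, fs)
  x <- signal::filtfilt(filt, x)
  x / stats::sd(x)
}

# Constant phase rotation applied to every positive-frequency component
# (negative frequencies get the conjugate rotation, keeping the result real).
phase_shift <- function(x, phase_lag) {
  n0 <- length(x)
  m <- stats::nextn(n0, c(2, 3, 5))
  if (m > n0) x <- c(x, numeric(m - n0))  # zero-pad to a composite length
  n <- length(x)
  X <- stats::fft(x)
  half <- if (n %% 2 == 0) n / 2 else (n + 1) / 2
  rot <- rep(1 + 0i, n)
  if (half >= 2) rot[2:half] <- exp(-1i * phase_lag)
  if (n %% 2 == 0 && n > 2) rot[(n / 2 + 2):n] <- exp(1i * phase_lag)
  else if (n %% 2 == 1 && n > 1) rot[(half + 1):n] <- exp(1i * phase_lag)
  Re(stats::fft(X * rot, inverse = TRUE))[seq_len(n0)] / n
}

# Smooth blink template: raised-cosine bump, ~300 ms wide.
blink_template <- function(fs, width_s = 0.3, amp_uv = 120) {
  n <- round(width_s * fs)
  amp_uv * (0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)))
}

#' Generate one synthetic EEG recording
#'
#' Per-channel 1/f background at the cohort's sampling rate; the planted
#' amplitude effects rescale the named band at the named channels for the
#' high-vulnerability group; coupling effects add a shared band-limited
#' carrier to both channels of each pair with a constant phase lag. Two EOG
#' channels carry noise plus blink transients that also leak into the
#' frontal scalp channels. Deterministic per `(spec$seed, subject_seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param group "high" or "low".
#' @param subject_seed integer subject stream index.
#' @param events optional SART event table; when supplied the recording is
#'   sized to cover the task ([sart_duration_s()]) instead of
#'   `rest_duration_s`.
#' @return An `eeg_recording` (34 channels: 32 scalp + EOG1/EOG2).
#' @export
generate_recording <- function(spec, group = c("high", "low"),
                               subject_seed = 1L, events = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  mont <- build_montage()
  dur <- if (!is.null(events) && nrow(events) > 0) {
    sart_duration_s(events)
  } else spec$rest_duration_s
  n <- round(dur * spec$fs)
  ch_names <- c(mont$channel_names, "EOG1", "EOG2")
  roles <- c(rep("scalp", 32), "eog", "eog")

  for (a in spec$effect$amplitude) montage_check_channels(mont, a$channel)
  for (cp in spec$effect$coupling) montage_check_channels(mont, cp$pair)

  with_seed(derive_seed(spec$seed, subject_seed), {
    data <- matrix(0, nrow = length(ch_names), ncol = n)
    for (i in seq_along(ch_names)) {
      data[i, ] <- one_over_f_noise(n, spec$fs, spec$noise_exponent,
                                    spec$noise_sd_uv)
    }
    rownames(data) <- ch_names

    if (group == "high") {
      for (a in spec$effect$amplitude) {
        band <- as_band(a$band)
        filt <- butter_bandpass(band$low_hz, band$high_hz, spec$fs)
        x <- data[a$channel, ]
        data[a$channel, ] <- x + (a$factor - 1) * signal::filtfilt(filt, x)
      }
    }
    for (cp in spec$effect$coupling) {
      target <- if (is.null(cp$group)) "high" else cp$group
      if (target != group) next
      s <- band_carrier(n, spec$fs, cp$band) * cp$mix * spec$noise_sd_uv
      data[cp$pair[1], ] <- data[cp$pair[1], ] + s
      data[cp$pair[2], ] <- data[cp$pair[2], ] + phase_shift(s, cp$phase_lag)
    }

    if (spec$blink_rate > 0 && n > spec$fs) {
      tmpl <- blink_template(spec$fs)
      n_blinks <- stats::rpois(1, spec$blink_rate * dur)
      if (n_blinks > 0) {
        starts <- sort(sample.int(n - length(tmpl), n_blinks, replace = TRUE))
        frontal <- match(c("Fp1", "Fp2", "AF3", "AF4"), ch_names)
        eog <- match(c("EOG1", "EOG2"), ch_names)
        for (s0 in starts) {
          idx <- s0:(s0 + length(tmpl) - 1)
          for (e in eog) data[e, idx] <- data[e, idx] + tmpl
          for (f in frontal) data[f, idx] <- data[f, idx] + 0.4 * tmpl
        }
      }
    }

    new_recording(data, spec$fs, ch_names, roles,
                  subject_id = sprintf("%s%02d", group, subject_seed),
                  group = group)
  })
}

# Questionnaire population parameters: per-group means and SDs of the
# screening questionnaires (PTQ, RRS, CES-D) and the negative-event writing
# ratings (intensity, frequency).
questionnaire_norms <- function() {
  list(
    high = c(PTQ = 45.85, RRS = 67.05, CESD = 51.65,
             intensity = 4.76, frequency = 4.35),
    high_sd = c(PTQ = 4.70, RRS = 7.34, CESD = 6.47,
                intensity = 0.97, frequency = 0.86),
    low = c(PTQ = 25.10, RRS = 41.75, CESD = 35.45,
            intensity = 4.11, frequency = 3.84),
    low_sd = c(PTQ = 8.33, RRS = 8.34, CESD = 3.71,
               intensity = 0.74, frequency = 0.83)
  )
}

#' Generate a questionnaire table for a cohort
#'
#' Scores are drawn from untruncated per-group normal distributions
#' (PTQ, RRS, CES-D, negative-event intensity and frequency). The writing
#' ratings (intensity, frequency) are missing for a configurable number of
#' subjects per group, emulating incomplete writing manipulations
#' (default 3 high-group, 1 low-group).
#'
#' @param n_high,n_low subjects per group.
#' @param seed integer seed.
#' @param missing_high,missing_low subjects with missing intensity/frequency;
#'   the defaults (3 and 1) are capped so at least two observed values
#'   remain per group in small cohorts.
#' @param norms population means/SDs as from `questionnaire_norms()`.
#' @return data.frame: `subject_id`, `group`, `PTQ`, `RRS`, `CESD`,
#'   `intensity`, `frequency`.
#' @export
generate_questionnaires <- function(n_high = 20L, n_low = 20L, seed = 1L,
                                    missing_high = NULL, missing_low = NULL,
                                    norms = questionnaire_norms()) {
  if (is.null(missing_high)) missing_high <- min(3L, max(0L, n_high - 2L))
  if (is.null(missing_low)) missing_low <- min(1L, max(0L, n_low - 2L))
  assert_scalar_num(missing_high, "missing_high", 0, n_high)
  assert_scalar_num(missing_low, "missing_low", 0, n_low)
  with_seed(derive_seed(seed, 999L), {
    draw <- function(n, mu, sd) round(stats::rnorm(n, mu, sd), 2)
    mk <- function(group, n, mu, sd, n_miss) {
      df <- data.frame(
        subject_id = sprintf("%s%02d", group, seq_len(n)),
        group = group,
        PTQ = draw(n, mu["PTQ"], sd["PTQ"]),
        RRS = draw(n, mu["RRS"], sd["RRS"]),
        CESD = draw(n, mu["CESD"], sd["CESD"]),
        intensity = draw(n, mu["intensity"], sd["intensity"]),
        frequency = draw(n, mu["frequency"], sd["frequency"]),
        stringsAsFactors = FALSE
      )
      if (n_miss > 0) {
        miss <- sample.int(n, n_miss)
        df$intensity[miss] <- NA_real_
        df$frequency[miss] <- NA_real_
      }
      df
    }
    rbind(
      mk("high", n_high, norms$high, norms$high_sd, missing_high),
      mk("low", n_low, norms$low, norms$low_sd, missing_low)
    )
  })
}

#' Generate a full synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param events optional SART event table applied to every subject (task
#'   cohorts); NULL for resting cohorts.
#' @return list with `recordings` (list of `eeg_recording`) and
#'   `questionnaires` (data.frame).
#' @export
generate_cohort <- function(spec, events = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- c(
    lapply(seq_len(spec$n_high), function(i) {
      generate_recording(spec, "high", subject_seed = i, events = events)
    }),
    lapply(seq_len(spec$n_low), function(i) {
      generate_recording(spec, "low", subject_seed = spec$n_high + i,
                         events = events)
    })
  )
  # keep subject ids unique across groups
  for (i in seq_len(spec$n_low)) {
    recs[[spec$n_high + i]]$subject_id <- sprintf("low%02d", i)
  }
  q <- generate_questionnaires(spec$n_high, spec$n_low, seed = spec$seed)
  list(recordings = recs, questionnaires = q)
}
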