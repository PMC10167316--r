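short_spec <- function(..., dur = 8) {
  cohort_spec(n_high = 2, n_low = 2, rest_duration_s = dur, seed = 42, ...)
}

test_that("zero noise and no effects give an all-zero recording", {
  spec <- short_spec(noise_sd_uv = 0, blink_rate = 0)
  rec <- generate_recording(spec, "high", 1)
  expect_true(all(rec$data == 0))
})

test_that("recordings are bit-identical for identical seeds", {
  spec <- short_spec()
  a <- generate_recording(spec, "high", 3)
  b <- generate_recording(spec, "high", 3)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, generate_recording(spec, "high", 4)$data))
})

test_that("unknown effect channels are rejected", {
  spec <- short_spec(effect = effect_spec(
    amplitude = list(list(channel = "XX9", band = "delta", factor = 1.5))))
  expect_error(generate_recording(spec, "high", 1), "unknown channel")
})

test_that("background has a falling (1/f-like) spectrum", {
  spec <- short_spec(dur = 16, blink_rate = 0)
  rec <- generate_recording(spec, "low", 1)
  w <- vulneeg:::welch_psd(rec$data["Cz", , drop = FALSE], rec$fs)
  lowp <- mean(w$psd[w$freq >= 1 & w$freq < 4, 1])
  highp <- mean(w$psd[w$freq >= 20 & w$freq < 40, 1])
  expect_gt(lowp, 5 * highp)
})

test_that("planted amplitude effect raises band power only where planted", {
  eff <- effect_spec(amplitude = list(
    list(channel = "O2", band = "delta", factor = 1.5)))
  spec <- short_spec(effect = eff, dur = 16, blink_rate = 0)
  hi <- generate_recording(spec, "high", 1)
  lo <- generate_recording(spec, "low", 1)  # same stream index, no effect
  p_hi <- band_power(rest_epochs(hi, 2), "delta")
  p_lo <- band_power(rest_epochs(lo, 2), "delta")
  expect_gt(p_hi["O2"] / p_lo["O2"], 1.5)      # amplitude x1.5 => power x2.25
  expect_lt(abs(log(p_hi["Oz"] / p_lo["Oz"])), log(1.5))
})

test_that("coupling effect synchronises only the planted pair", {
  eff <- effect_spec(coupling = list(
    list(pair = c("F3", "P7"), band = "alpha", phase_lag = pi / 2, mix = 0.8)))
  spec <- short_spec(effect = eff, dur = 10, blink_rate = 0)
  ep <- rest_epochs(generate_recording(spec, "high", 2), 2)
  pli <- connectivity_phase(ep, "alpha")$pli$values
  expect_gt(pli["F3", "P7"], 0.5)
  expect_lt(pli["F3", "C4"], 0.3)
})

test_that("questionnaire tables follow the group norms and missingness", {
  q <- generate_questionnaires(20, 20, seed = 1)
  hi <- q[q$group == "high", ]; lo <- q[q$group == "low", ]
  # sample means within 3 standard errors of the population values
  expect_lt(abs(mean(hi$PTQ) - 45.85), 3 * 4.70 / sqrt(20))
  expect_lt(abs(mean(lo$PTQ) - 25.10), 3 * 8.33 / sqrt(20))
  expect_equal(sum(!is.na(q$intensity)), 36)  # 40 - 3 - 1
  expect_equal(sum(is.na(hi$intensity)), 3)
  expect_equal(sum(is.na(lo$frequency)), 1)
  # missing writing ratings co-occur (one incomplete manipulation per subject)
  expect_identical(is.na(q$intensity), is.na(q$frequency))
})

test_that("cohort size and invalid specs are enforced", {
  expect_error(cohort_spec(n_high = 0), "out of range")
  expect_error(cohort_spec(fs = 60), "out of range")
  spec <- short_spec()
  coh <- generate_cohort(spec)
  expect_length(coh$recordings, 4)
  expect_equal(sort(unique(coh$questionnaires$group)), c("high", "low"))
  expect_equal(vapply(coh$recordings, function(r) r$group, ""),
               c("high", "high", "low", "low"))
})

test_that("effect_spec validates factors, mix and phase lag", {
  expect_error(effect_spec(amplitude = list(
    list(channel = "O2", band = "delta", factor = 0))), "factor")
  expect_error(effect_spec(coupling = list(
    list(pair = c("F3", "F4"), band = "alpha", phase_lag = 0, mix = 1.2))),
    "mix")
  expect_error(effect_spec(coupling = list(
    list(pair = c("F3", "F4"), band = "alpha", phase_lag = 4, mix = 0.5))),
    "phase_lag")
})
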