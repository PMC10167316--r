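fs <- 512

make_rec <- function(data, roles = rep("scalp", nrow(data)),
                     names = sprintf("ch%02d", seq_len(nrow(data)))) {
  vulneeg:::new_recording(data, fs, names, roles, "s01", "high")
}

test_that("band-pass removes DC, passes 10 Hz, attenuates per design", {
  n <- 16 * fs
  rec <- make_rec(rbind(rep(5, n), sine_wave(10, fs, n),
                        sine_wave(45, fs, n)))
  out <- bandpass_filter(rec, 0.5, 40)
  mid <- (6 * fs):(10 * fs)
  expect_lt(max(abs(out$data[1, mid])), 0.05)
  amp10 <- sqrt(2 * mean(out$data[2, mid]^2))
  expect_lt(abs(amp10 - 1), 0.05)
  # forward-backward filtering realises |H(f)|^2 of the designed filter
  bb <- signal::butter(4, c(0.5, 40) / (fs / 2), type = "pass")
  h <- signal::freqz(bb, n = 8192, Fs = fs)
  expected <- abs(h$h[which.min(abs(h$f - 45))])^2
  amp45 <- sqrt(2 * mean(out$data[3, mid]^2))
  expect_lt(abs(amp45 - expected) / expected, 0.02)
})

test_that("filter is zero-phase: symmetric pulse stays symmetric", {
  n <- 4 * fs
  x <- exp(-((seq_len(n) - n / 2)^2) / (2 * (fs / 20)^2))
  rec <- make_rec(matrix(x, 1))
  out <- bandpass_filter(rec, 0.5, 40)
  expect_equal(which.max(out$data[1, ]), n / 2)
})

test_that("filter rejects invalid cutoffs and preserves length", {
  rec <- make_rec(matrix(rnorm(fs), 1))
  expect_error(bandpass_filter(rec, 0, 40), "band edges")
  expect_error(bandpass_filter(rec, 10, 300), "band edges")
  expect_equal(ncol(bandpass_filter(rec, 0.5, 40)$data), fs)
})

test_that("segmentation follows the round(t*fs) half-open convention", {
  rec <- make_rec(matrix(seq_len(10 * fs), 1))
  ev <- data.frame(onset_s = c(2, 5, 0.1, 9.5))
  ep <- segment_epochs(rec, ev, -0.5, 1.3)
  expect_equal(dim(ep$data)[3], 922)          # round(1.8 * 512)
  expect_equal(dim(ep$data)[1], 2)            # 0.1 s and 9.5 s out of bounds
  expect_equal(attr(ep, "n_dropped"), 2)
  # first kept sample is onset + round(-0.5*fs) (0-based), +1 for R indexing
  expect_equal(ep$data[1, 1, 1], unname(rec$data[1, round(2 * fs) - 256 + 1]))
  expect_equal(ep$events$onset_s, c(2, 5))
})

test_that("empty event lists give an empty epoch set, in metadata order", {
  rec <- make_rec(matrix(rnorm(2 * 6 * fs), 2))
  ep0 <- segment_epochs(rec, data.frame(onset_s = numeric(0)))
  expect_equal(dim(ep0$data)[1], 0)
  ev <- data.frame(onset_s = seq(1, 4, by = 0.5))
  ep <- segment_epochs(rec, ev, -0.2, 0.3)
  expect_equal(dim(ep$data)[1], nrow(ev))
  expect_equal(ep$events$onset_s, ev$onset_s)
})

test_that("baseline correction subtracts the window mean exactly", {
  ep <- make_epochs(array(5, c(2, 3, 256)), fs = fs, tmin_s = -0.25)
  out <- baseline_correct(ep)
  expect_true(all(out$data == 0))

  set.seed(1)
  ep <- make_epochs(array(rnorm(4 * 3 * 922), c(4, 3, 922)), fs = fs,
                    tmin_s = -0.5)
  out <- baseline_correct(ep, c(-0.5, 0))
  tt <- epoch_times(ep)
  sel <- tt >= -0.5 & tt < 0
  for (tr in 1:4) for (ch in 1:3) {
    expect_equal(out$data[tr, ch, ],
                 ep$data[tr, ch, ] - mean(ep$data[tr, ch, sel]))
    expect_lt(abs(mean(out$data[tr, ch, sel])), 1e-9)
  }
  expect_error(baseline_correct(ep, c(-0.5, 0.5)), "within")
})

test_that("trimming crops to the stated counts and is idempotent", {
  set.seed(2)
  ep <- make_epochs(array(rnorm(2 * 2 * 922), c(2, 2, 922)), fs = fs,
                    tmin_s = -0.5)
  tr <- trim_epochs(ep, -0.2, 1.3)
  expect_equal(dim(tr$data)[3], 768)           # 1.5 * 512
  expect_lt(abs(tr$tmin_s - (-0.2)), 1 / fs)  # nearest sample-grid point
  expect_identical(trim_epochs(ep, -0.5, ep$tmin_s + 922 / fs)$data, ep$data)
  two_step <- trim_epochs(trim_epochs(ep, -0.3, 1.3), -0.2, 1.0)
  one_step <- trim_epochs(ep, -0.2, 1.0)
  expect_identical(two_step$data, one_step$data)
  expect_error(trim_epochs(ep, -0.7, 1.3), "not nested")
})

test_that("peak-to-peak rejection removes exactly the planted artifacts", {
  set.seed(3)
  n_tr <- 12
  data <- array(rnorm(n_tr * 4 * 256, sd = 5), c(n_tr, 4, 256))
  planted <- c(2, 7, 11)
  for (tr in planted) data[tr, 3, 100] <- data[tr, 3, 100] + 500
  ep <- make_epochs(data, fs = fs)
  res <- reject_artifacts(ep, 150)
  expect_equal(res$report$n_total, n_tr)
  expect_equal(res$report$n_rejected, length(planted))
  expect_equal(which(res$report$reason == "ptp_exceeded"), planted)
  expect_equal(res$report$proportion_rejected, length(planted) / n_tr)
  # clean data: nothing rejected
  clean <- reject_artifacts(make_epochs(array(rnorm(8 * 2 * 64, sd = 5),
                                              c(8, 2, 64))), 150)
  expect_equal(clean$report$proportion_rejected, 0)
})

test_that("rejection ignores EOG channels", {
  data <- array(0, c(2, 3, 64))
  data[1, 3, 10] <- 500  # spike on the EOG channel only
  ep <- make_epochs(data, roles = c("scalp", "scalp", "eog"))
  res <- reject_artifacts(ep, 150)
  expect_equal(res$report$n_rejected, 0)
})

test_that("bad-channel interpolation averages the montage neighbors", {
  mont <- build_montage(4)
  ep <- make_montage_epochs(3, 128)
  set.seed(4)
  ep$data <- array(rnorm(length(ep$data)), dim(ep$data))
  out <- interpolate_bad_channels(ep, "Pz", mont)
  i_pz <- match("Pz", ep$channel_names)
  i_nb <- match(mont$neighbors$Pz, ep$channel_names)
  for (tr in 1:3) {
    expect_equal(out$data[tr, i_pz, ],
                 colMeans(ep$data[tr, i_nb, , drop = TRUE]))
  }
  # untouched channels identical; empty bad list is the identity
  expect_identical(out$data[, match("Cz", ep$channel_names), ],
                   ep$data[, match("Cz", ep$channel_names), ])
  expect_identical(interpolate_bad_channels(ep, character(0), mont), ep)
  # neighbors carrying the same signal reproduce it exactly
  ep2 <- make_montage_epochs(1, 64)
  c_t <- sine_wave(7, fs, 64)
  for (nb in mont$neighbors$Oz) ep2$data[1, match(nb, ep2$channel_names), ] <- c_t
  out2 <- interpolate_bad_channels(ep2, "Oz", mont)
  expect_equal(out2$data[1, match("Oz", ep2$channel_names), ], c_t)
  expect_error(interpolate_bad_channels(ep, "nope", mont), "unknown channel")
})

test_that("average re-reference zeroes the scalp mean and spares EOG", {
  set.seed(5)
  data <- array(rnorm(2 * 5 * 128), c(2, 5, 128))
  roles <- c(rep("scalp", 4), "eog")
  ep <- make_epochs(data, roles = roles)
  common <- sine_wave(3, fs, 128, amp = 10)
  for (ch in 1:4) ep$data[1, ch, ] <- ep$data[1, ch, ] + common
  out <- rereference_average(ep)
  for (tr in 1:2) {
    expect_lt(max(abs(colMeans(out$data[tr, 1:4, , drop = TRUE]))), 1e-9)
  }
  expect_identical(out$data[, 5, ], ep$data[, 5, ])
  # direct recomputation oracle
  for (tr in 1:2) for (ch in 1:4) {
    expect_equal(out$data[tr, ch, ],
                 ep$data[tr, ch, ] - colMeans(ep$data[tr, 1:4, , drop = TRUE]))
  }
  # re-referencing removes a common-mode signal entirely: the common sine
  # contributes nothing to the referenced trial 1 relative to trial 1 without it
  ep_no <- make_epochs(data, roles = roles)
  out_no <- rereference_average(ep_no)
  expect_equal(out$data[1, 1:4, ], out_no$data[1, 1:4, ], tolerance = 1e-9)
})

test_that("preprocessing operations are pure", {
  set.seed(6)
  data <- array(rnorm(2 * 3 * 922), c(2, 3, 922))
  ep <- make_epochs(data, fs = fs, tmin_s = -0.5)
  snapshot <- ep$data + 0
  invisible(baseline_correct(ep))
  invisible(trim_epochs(ep, -0.2, 1.0))
  invisible(reject_artifacts(ep, 150))
  invisible(rereference_average(ep))
  expect_identical(ep$data, snapshot)
})

test_that("full default chain runs and produces the analysis window", {
  spec <- cohort_spec(n_high = 1, n_low = 1, rest_duration_s = 5, seed = 2)
  ev <- generate_sart_events(1, 6, probe_rate = 0, seed = 2)
  rec <- generate_recording(spec, "high", 1, events = ev)
  res <- preprocess_recording(rec, ev)
  expect_equal(dim(res$epochs$data)[3], 768)
  expect_lte(res$report$n_rejected, res$report$n_total)
  expect_lt(abs(res$epochs$tmin_s - (-0.2)), 1 / fs)
})
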