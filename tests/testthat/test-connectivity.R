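fs <- 512

test_that("correlation connectivity: self 1, antiphase -1, null near 0", {
  set.seed(20)
  n <- 2 * fs
  x <- rnorm(n)
  ep <- make_epochs(array(rbind(x, -x), c(1, 2, n)))
  cm <- connectivity_correlation(ep, "raw")
  expect_equal(diag(cm$values), c(ch01 = 1, ch02 = 1))
  expect_equal(cm$values[1, 2], -1)
  # independent channels over 50 trials: mean r close to zero
  data <- array(rnorm(50 * 2 * 256), c(50, 2, 256))
  cmn <- connectivity_correlation(make_epochs(data), "raw")
  expect_lt(abs(cmn$values[1, 2]), 0.05)
  expect_error(connectivity_correlation(
    make_epochs(array(0, c(1, 2, 64))), "raw"), "zero-variance")
})

test_that("coherence: identical signals give magnitude 1, imaginary 0", {
  set.seed(21)
  n <- 4 * fs
  x <- rnorm(n)
  ep <- make_epochs(array(rbind(x, x), c(1, 2, n)))
  co <- connectivity_coherence(ep, "alpha")
  expect_equal(co$coherence_mag$values[1, 2], 1, tolerance = 1e-9)
  expect_equal(co$coherence_imag$values[1, 2], 0, tolerance = 1e-9)
  expect_equal(diag(co$coherence_mag$values), c(ch01 = 1, ch02 = 1))
  expect_equal(diag(co$coherence_imag$values), c(ch01 = 0, ch02 = 0))
})

test_that("a quarter-period lag shows up in the imaginary coherence", {
  n <- 8 * fs
  x <- vulneeg:::band_carrier(n, fs, "alpha")      # ~10.5 Hz center
  lag <- round(fs / 10.5 / 4)                      # quarter period
  y <- c(x[(lag + 1):n], x[1:lag])
  ep <- make_epochs(array(rbind(x, y), c(1, 2, n)))
  co <- connectivity_coherence(ep, "alpha")
  expect_gt(abs(co$coherence_imag$values[1, 2]), 0.7)
  expect_gt(co$coherence_mag$values[1, 2], 0.9)
})

test_that("null coherence bias matches the 1/L law", {
  # for independent noise, E[|coh|^2] ~ 1/L with L averaged segments
  set.seed(22)
  msq <- function(n_trials) {
    data <- array(rnorm(n_trials * 2 * 1024), c(n_trials, 2, 1024))
    co <- connectivity_coherence(make_epochs(data), "raw", window_sec = 2)
    co$coherence_mag$values[1, 2]^2
  }
  v8 <- mean(replicate(6, msq(8)))     # L = 8 trials x 1 window
  v32 <- mean(replicate(6, msq(32)))
  expect_lt(abs(v8 - 1 / 8) / (1 / 8), 0.5)
  expect_lt(abs(v32 - 1 / 32) / (1 / 32), 0.5)
  expect_gt(v8 / v32, 2.5)             # quadrupling L shrinks the bias
})

test_that("PLV/PLI: constant 90-degree lag vs zero lag", {
  n <- 4 * fs
  x <- vulneeg:::band_carrier(n, fs, "alpha")
  y90 <- vulneeg:::phase_shift(x, pi / 2)
  ep90 <- make_epochs(array(rbind(x, y90), c(1, 2, n)))
  ph <- connectivity_phase(ep90, "alpha")
  expect_gt(ph$plv$values[1, 2], 0.98)
  expect_gt(ph$pli$values[1, 2], 0.98)
  ep0 <- make_epochs(array(rbind(x, x), c(1, 2, n)))
  ph0 <- connectivity_phase(ep0, "alpha")
  expect_gt(ph0$plv$values[1, 2], 0.98)
  expect_lt(ph0$pli$values[1, 2], 0.02)
  expect_error(connectivity_phase(ep0, "raw"), "narrow band")
})

test_that("null PLV shrinks with the number of samples", {
  set.seed(23)
  null_plv <- function(n_trials) {
    data <- array(0, c(n_trials, 2, 1024))
    for (tr in seq_len(n_trials)) {
      data[tr, 1, ] <- vulneeg:::band_carrier(1024, fs, "alpha")
      data[tr, 2, ] <- vulneeg:::band_carrier(1024, fs, "alpha")
    }
    connectivity_phase(make_epochs(data), "alpha")$plv$values[1, 2]
  }
  small <- mean(replicate(4, null_plv(2)))
  large <- mean(replicate(4, null_plv(16)))
  expect_lt(large, small)
  expect_lt(large, 0.35)
})

test_that("connectivity matrices satisfy the type invariants", {
  set.seed(24)
  data <- array(rnorm(4 * 5 * 1024), c(4, 5, 1024))
  ep <- make_epochs(data)
  cm <- connectivity_correlation(ep, "alpha")
  co <- connectivity_coherence(ep, "alpha")
  ph <- connectivity_phase(ep, "alpha")
  for (m in list(cm, co$coherence_mag, co$coherence_imag, ph$plv, ph$pli)) {
    expect_equal(m$values, t(m$values))
  }
  expect_true(all(cm$values >= -1 & cm$values <= 1))
  expect_true(all(co$coherence_mag$values >= 0 &
                    co$coherence_mag$values <= 1 + 1e-9))
  expect_true(all(ph$plv$values >= 0 & ph$plv$values <= 1 + 1e-9))
  expect_true(all(ph$pli$values >= 0 & ph$pli$values <= 1 + 1e-9))
  expect_equal(unname(diag(ph$pli$values)), rep(0, 5))
  expect_equal(unname(diag(ph$plv$values)), rep(1, 5))
})

test_that("PLI is robust to zero-lag common signals, correlation is not", {
  set.seed(25)
  n <- 4 * fs; n_trials <- 12
  d_ind <- array(0, c(n_trials, 2, n)); d_com <- d_ind
  for (tr in seq_len(n_trials)) {
    b1 <- vulneeg:::band_carrier(n, fs, "alpha")
    b2 <- vulneeg:::band_carrier(n, fs, "alpha")
    common <- 2 * vulneeg:::band_carrier(n, fs, "alpha")
    d_ind[tr, 1, ] <- b1; d_ind[tr, 2, ] <- b2
    d_com[tr, 1, ] <- b1 + common; d_com[tr, 2, ] <- b2 + common
  }
  pli_ind <- connectivity_phase(make_epochs(d_ind), "alpha")$pli$values[1, 2]
  pli_com <- connectivity_phase(make_epochs(d_com), "alpha")$pli$values[1, 2]
  cor_ind <- connectivity_correlation(make_epochs(d_ind),
                                      "alpha")$values[1, 2]
  cor_com <- connectivity_correlation(make_epochs(d_com),
                                      "alpha")$values[1, 2]
  expect_lt(abs(pli_com - pli_ind), 0.05)
  expect_gt(abs(cor_com - cor_ind), 0.2)
})
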