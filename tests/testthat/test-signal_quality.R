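test_that("flat-line, NaN and saturated sub-windows are flagged noisy", {
  fs <- 125
  expect_false(assess_subwindow(rep(0, 5 * fs), fs)$clean)
  expect_false(assess_subwindow(rep(1.3, 5 * fs), fs)$clean)
  expect_false(assess_subwindow(c(rep(NA_real_, 200), rnorm(425)), fs)$clean)

  seg <- synth_segment("NSR")
  win <- seg$samples[1:(5 * fs)]
  expect_true(assess_subwindow(win, fs)$clean)
  # hard saturation pins a mass of samples at the rails
  expect_false(assess_subwindow(pmin(pmax(win, -0.05), 0.15), fs)$clean)
  expect_error(assess_subwindow(win, -1), "positive")
  expect_error(assess_subwindow(win[1:100], fs), "2 s")
})

test_that("adding noise never turns a noisy verdict clean across an SNR grid", {
  seg <- synth_segment("NSR", noise = noise_config(0, 0, 0, 0))
  fs <- seg$fs
  sigpow <- mean((seg$samples - mean(seg$samples))^2)
  set.seed(42)
  eps <- rnorm(length(seg$samples))
  frac <- sapply(c(Inf, 20, 10, 6, 0, -6, -12), function(snr) {
    nsd <- if (is.infinite(snr)) 0 else sqrt(sigpow / 10^(snr / 10))
    assess_segment(seg$samples + nsd * eps, fs)$clean_fraction
  })
  expect_equal(frac[1], 1)                      # noise-free: fully clean
  expect_true(all(diff(frac) <= 0))             # monotone in decreasing SNR
  expect_lt(frac[length(frac)], 0.5)            # -12 dB: unusable
  sn6 <- assess_segment(seg$samples + sqrt(sigpow / 10^(-6 / 10)) * eps, fs)
  expect_false(sn6$usable)                      # -6 dB white noise: noisy
})

test_that("segment usability requires a strict majority of clean sub-windows", {
  seg <- synth_segment("NSR")
  fs <- seg$fs
  zero_first <- function(k) {
    x <- seg$samples
    if (k > 0) x[1:(k * 5 * fs)] <- 0
    assess_segment(x, fs)
  }
  q12 <- zero_first(12)   # 12/24 clean: not a strict majority
  expect_equal(q12$clean_fraction, 0.5)
  expect_false(q12$usable)
  q11 <- zero_first(11)   # 13/24 clean
  expect_equal(q11$clean_fraction, 13 / 24)
  expect_true(q11$usable)
  q0 <- zero_first(0)
  expect_equal(q0$clean_fraction, 1)
  expect_true(q0$usable)
})

test_that("record analyzability needs one run of 3 consecutive usable segments", {
  expect_true(record_analyzable(c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  expect_false(record_analyzable(rep(c(TRUE, FALSE), 10)))
  expect_true(record_analyzable(rep(TRUE, 5)))
  expect_false(record_analyzable(logical(0)))
  expect_false(record_analyzable(c(TRUE, TRUE, FALSE, TRUE, TRUE)))
  expect_true(record_analyzable(c(TRUE, TRUE, FALSE, TRUE, TRUE), k = 2))
})
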