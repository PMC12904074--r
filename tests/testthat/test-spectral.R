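# Welch PSD, band power, coherence and lagged cross-correlation.

test_that("Welch PSD recovers tone power and satisfies Parseval", {
  fs <- 1000
  x <- toneSignal(8, 10)
  p <- welchPSD(x, fs)
  expect_equal(p$freqs_hz[which.max(p$psd)], 8)
  df <- diff(p$freqs_hz)[1]
  expect_equal(sum(p$psd) * df, 0.5, tolerance = 0.02)
  expect_true(all(welchPSD(numeric(5000), fs)$psd == 0))
  # Parseval on white noise
  set.seed(4)
  w <- rnorm(10 * fs)
  pw <- welchPSD(w, fs)
  expect_equal(sum(pw$psd) * diff(pw$freqs_hz)[1], var(w), tolerance = 0.05)
  expect_error(welchPSD(rnorm(100), fs), "too short")
})

test_that("Welch PSD agrees with the smoothed-periodogram oracle", {
  # independent route: stats::spec.pgram on the same realization
  set.seed(5)
  fs <- 200
  x <- toneSignal(30, 20, fs = fs, amp = 2) + rnorm(20 * fs)
  p <- welchPSD(x, fs, segment_s = 2)
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 15,
                          taper = 0.1, plot = FALSE, detrend = FALSE)
  # compare band-integrated tone power (density conventions differ by 2x
  # one-sidedness; spec.pgram spreads variance over frequency in Hz)
  own <- .bandIntegral(p$freqs_hz, p$psd, 25, 35)
  oracle <- 2 * sum(sp$spec[sp$freq >= 25 & sp$freq <= 35]) *
    diff(sp$freq)[1]
  expect_equal(own, oracle, tolerance = 0.1)
})

test_that("band power is calibrated in dB and additive under scaling", {
  fs <- 1000
  x <- toneSignal(8, 10)
  bp <- bandPowerDb(x, fs, "theta")
  expect_equal(bp$power_db, 10 * log10(0.5), tolerance = 0.01)
  expect_lt(bandPowerDb(x, fs, "gamma")$power_db, bp$power_db - 40)
  # 10 Hz belongs to theta (3-12 Hz)
  expect_gt(bandPowerDb(toneSignal(10, 10), fs, "theta")$power_db, -4)
  # doubling amplitude adds 20*log10(2) dB in every band
  set.seed(6)
  y <- rnorm(10 * fs)
  for (b in c("theta", "beta", "gamma"))
    expect_equal(bandPowerDb(2 * y, fs, b)$power_db -
                 bandPowerDb(y, fs, b)$power_db,
                 20 * log10(2), tolerance = 0.05)
  z <- bandPowerDb(numeric(10 * fs), fs, "theta")
  expect_identical(z$power_db, -Inf)
  expect_true(z$zero_signal)
})

test_that("coherence is 1 for identical signals, symmetric, and follows the SNR law", {
  fs <- 500
  set.seed(7)
  x <- rnorm(60 * fs)
  co <- bandCoherence(x, x, fs)
  expect_true(all(abs(co$msc[-1] - 1) < 1e-9))
  expect_equal(unname(co$band_means), rep(1, 3))
  # symmetry
  y <- rnorm(60 * fs)
  co_xy <- bandCoherence(x, y, fs)
  co_yx <- bandCoherence(y, x, fs)
  expect_equal(co_xy$msc, co_yx$msc, tolerance = 1e-12)
  # msc = SNR/(1+SNR) for y = x + independent noise
  set.seed(8)
  s <- rnorm(100 * fs)
  for (snr in c(0.25, 1, 4)) {
    yn <- s + rnorm(length(s), sd = 1 / sqrt(snr))
    msc_band <- bandCoherence(s, yn, fs, summary = "msc")$band_means
    expect_lt(abs(msc_band[["theta"]] - snr / (1 + snr)), 0.05)
  }
  # independent signals, 16 segments: low band summary (finite-sample bias)
  set.seed(9)
  a <- rnorm(17 * fs)
  b <- rnorm(17 * fs)
  expect_lt(max(bandCoherence(a, b, fs)$band_means), 0.3)
  expect_warning(bandCoherence(rnorm(5 * fs), rnorm(5 * fs), fs),
                 "biased")
})

test_that("maxXCorr recovers delays, ignores sign, and bounds the null", {
  fs <- 1000
  set.seed(10)
  x <- rnorm(10 * fs)
  for (k in c(-25, 0, 10)) {
    y <- if (k >= 0) c(rep(0, k), x[1:(length(x) - k)]) else
      c(x[(1 - k):length(x)], rep(0, -k))
    r <- maxXCorr(x, y, fs, 0.5)
    expect_equal(r$peak_lag_s, k / fs)
    expect_gt(r$peak_abs, 0.99)
  }
  inv <- maxXCorr(x, -x, fs, 0.5)
  expect_equal(inv$peak_abs, 1)
  expect_equal(inv$peak_lag_s, 0)
  expect_error(maxXCorr(rep(1, 1000), rnorm(1000), fs, 0.1), "constant")
  # lag-0 value equals the Pearson correlation
  set.seed(11)
  a <- rnorm(5000); b <- 0.3 * a + rnorm(5000)
  r0 <- maxXCorr(a, b, fs, 0.2)
  expect_equal(r0$r[r0$lags_s == 0], cor(a, b), tolerance = 1e-10)
  # independent-noise null stays small across seeds
  peaks <- vapply(1:20, function(s) {
    set.seed(100 + s)
    maxXCorr(rnorm(10 * fs), rnorm(10 * fs), fs, 0.5)$peak_abs
  }, numeric(1))
  expect_lt(max(peaks), 0.1)
})
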