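# Band-pass analytic signal, PAC, spike-phase locking, STA.

test_that("bandpassAnalytic keeps amplitude, cosine phase and zero lag", {
  fs <- 1000
  x <- toneSignal(8, 10)
  ab <- bandpassAnalytic(x, fs, "theta")
  mid <- 2000:8000
  expect_equal(mean(ab$amplitude[mid]), 1, tolerance = 0.02)
  expect_lt(sd(ab$amplitude[mid]), 0.02)
  # cosine-phase convention: phase ~ 0 at signal peaks
  peaks <- which(diff(sign(diff(x))) == -2) + 1
  peaks <- peaks[peaks > 2000 & peaks < 8000]
  expect_lt(max(abs(ab$phase[peaks])), 0.05)
  # instantaneous frequency ~ 8 Hz
  instf <- diff(.unwrap(ab$phase[mid])) * fs / (2 * pi)
  expect_equal(mean(instf), 8, tolerance = 0.05)
  # zero-phase filtering: no lag between filtered and raw narrowband signal
  expect_equal(maxXCorr(ab$filtered, x, fs, 0.2)$peak_lag_s, 0)
  expect_error(bandpassAnalytic(x[1:500], fs, "theta"), "too short")
})

test_that("bandpassAnalytic tracks a chirp's instantaneous frequency", {
  fs <- 1000
  t <- (0:(20 * fs - 1)) / fs
  f0 <- 4; f1 <- 11
  finst <- f0 + (f1 - f0) * t / max(t)
  x <- cos(2 * pi * cumsum(finst) / fs)
  ab <- bandpassAnalytic(x, fs, "theta")
  est <- diff(.unwrap(ab$phase)) * fs / (2 * pi)
  core <- 2000:(length(est) - 2000)
  expect_lt(max(abs(est[core] - finst[core]) / finst[core]), 0.05)
})

test_that("Tort modulation index has the right extremes and oracle value", {
  set.seed(12)
  n <- 50000
  phase <- runif(n, -pi, pi)
  # amplitude independent of phase -> MI ~ 0
  expect_lt(pacMI(phase, abs(rnorm(n)))$mi, 0.01)
  # all amplitude in one bin -> MI = 1
  amp1 <- as.numeric(phase > -pi & phase < -pi + 2 * pi / 18)
  expect_equal(pacMI(phase, amp1 + 1e-12)$mi, 1, tolerance = 1e-6)
  # MI invariant to amplitude scaling
  a <- abs(rnorm(n)) * (1 + 0.4 * cos(phase))
  expect_equal(pacMI(phase, a)$mi, pacMI(phase, 7.3 * a)$mi,
               tolerance = 1e-12)
  # quadrature oracle for the (1 + m cos(phi)) profile at m = 0.5
  m <- 0.5
  nb <- 18
  edges <- seq(-pi, pi, length.out = nb + 1)
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  prof <- 1 + m * cos(centers)
  prof <- prof / sum(prof)
  mi_oracle <- sum(prof * log(prof * nb)) / log(nb)
  amp <- (1 + m * cos(phase)) # noiseless generative profile
  pm <- pacMI(phase, amp)
  expect_equal(pm$mi, mi_oracle, tolerance = 0.15)
  expect_lt(abs(pm$preferred_phase), 0.2)
  expect_error(pacMI(runif(100, 0, 0.1), abs(rnorm(100))), "empty phase bin")
})

test_that("MI increases monotonically with planted coupling depth", {
  fs <- 1000
  depths <- c(0, 0.25, 0.5, 0.75, 1)
  rhos <- vapply(1:5, function(s) {
    mi <- vapply(depths, function(m) {
      oscs <- list(
        oscSpec("OB", "theta", 8, 40, id = "th"),
        oscSpec("OB", "gamma", 60, 15, id = "ga",
                amp_mod = list(phase_source = "th", depth = m,
                               preferred_phase = 0)))
      rec <- simulateLFP(oscs, 40, fs, noise = list(alpha = 1, sigma = 2),
                         seed = 400 + s)
      pacMI(bandpassAnalytic(lfpSignal(rec, "OB"), fs, "theta"),
            bandpassAnalytic(lfpSignal(rec, "OB"), fs, "gamma"))$mi
    }, numeric(1))
    cor(mi, depths, method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0.999))
})

test_that("comodulogram localizes planted theta-gamma coupling", {
  fs <- 1000
  oscs <- list(
    oscSpec("OB", "theta", 8, 40, id = "th"),
    oscSpec("OB", "gamma", 60, 15, id = "ga",
            amp_mod = list(phase_source = "th", depth = 0.8,
                           preferred_phase = 0)))
  rec <- simulateLFP(oscs, 60, fs, noise = list(alpha = 1, sigma = 1),
                     seed = 14)
  cm <- comodulogram(lfpSignal(rec, "OB"), lfpSignal(rec, "OB"), fs,
                     phase_freqs_hz = seq(4, 12, by = 2),
                     amp_freqs_hz = seq(40, 80, by = 10))
  k <- arrayInd(which.max(cm$mi), dim(cm$mi))
  expect_lte(abs(cm$phase_freqs_hz[k[1]] - 8), 2)
  expect_lte(abs(cm$amp_freqs_hz[k[2]] - 60), 10)
  # no coupling -> all cells small
  rec0 <- simulateLFP(list(oscSpec("OB", "theta", 8, 40, id = "th"),
                           oscSpec("OB", "gamma", 60, 15, id = "ga")),
                      60, fs, noise = list(alpha = 1, sigma = 1), seed = 15)
  cm0 <- comodulogram(lfpSignal(rec0, "OB"), lfpSignal(rec0, "OB"), fs,
                      phase_freqs_hz = c(6, 8, 10),
                      amp_freqs_hz = c(50, 60, 70))
  expect_lt(max(cm0$mi), 0.01)
  expect_error(
    comodulogram(rnorm(5000), rnorm(5000), fs, amp_freqs_hz = 495),
    "Nyquist")
})

test_that("spike-phase locking matches the von Mises Bessel-ratio oracle", {
  fs <- 1000
  rec <- simulateLFP(list(oscSpec("OB", "theta", 8, 50, id = "th")), 200,
                     fs, noise = list(alpha = 1, sigma = 0.5), seed = 16)
  rec <- simulateSpikes(rec, list(
    unitSpec("OB", 5, "theta", kappa = 2, mu = 1, unit_id = "locked"),
    unitSpec("OB", 5, "theta", kappa = 50, mu = -2, unit_id = "tight"),
    unitSpec("OB", 5, "theta", kappa = 0, unit_id = "poisson")), seed = 17)
  us <- spikeUnits(rec)
  x <- lfpSignal(rec, "OB")
  pl <- spikePhaseLocking(us[[1]], x, fs, "theta")
  expect_gt(pl$n_spikes, 500)
  expect_equal(pl$mrl, besselI(2, 1) / besselI(2, 0), tolerance = 0.05)
  expect_equal(pl$preferred_phase, 1, tolerance = 0.1)
  expect_true(classifyLocked(pl))
  tight <- spikePhaseLocking(us[[2]], x, fs, "theta")
  expect_equal(tight$preferred_phase, -2, tolerance = 0.1)
  expect_gt(tight$mrl, 0.9)
  unif <- spikePhaseLocking(us[[3]], x, fs, "theta")
  expect_lt(unif$mrl, 0.1)
})

test_that("mrl is rotation invariant and the Rayleigh null is calibrated", {
  set.seed(18)
  phi <- runif(300, -pi, pi)
  mrl <- function(p) Mod(mean(exp(1i * p)))
  expect_equal(mrl(phi), mrl(.wrapPhase(phi + 1.2345)), tolerance = 1e-12)
  # all spikes at one phase: mrl = 1, p -> 0
  expect_equal(rayleighP(1, 100), .Machine$double.xmin)
  # null p-values roughly uniform
  ps <- vapply(1:400, function(s) {
    set.seed(1000 + s)
    p <- runif(200, -pi, pi)
    rayleighP(mrl(p), 200)
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("classifyLocked applies the low-n guard", {
  res <- structure(list(unit_id = "u", band = defaultBands()[1, ],
                        n_spikes = 10, mrl = 0.99,
                        rayleigh_p = 1e-10, low_n = TRUE),
                   class = "PhaseLockResult")
  expect_false(classifyLocked(res))
  res$n_spikes <- 100
  expect_true(classifyLocked(res))
})

test_that("spike-triggered averages separate locked from unlocked units", {
  fs <- 1000
  x <- toneSignal(8, 60)
  peaks <- which(diff(sign(diff(x))) == -2) + 1
  u <- SpikeUnit("locked", "OB", peaks / fs)
  sta <- spikeTriggeredAverage(u, x, fs, window_s = 0.1, band = "theta")
  expect_equal(length(sta$sta), 2 * 0.1 * fs + 1)
  expect_equal(max(sta$sta), 1, tolerance = 0.02)  # coherent averaging
  expect_equal(sta$sta[101], 1, tolerance = 0.02)  # peak at the spike
  # incoherent averaging shrinks like 1/sqrt(n)
  set.seed(19)
  noise <- rnorm(600 * fs)
  t100 <- sort(runif(100, 1, 599))
  t400 <- sort(runif(400, 1, 599))
  a100 <- max(abs(spikeTriggeredAverage(SpikeUnit("a", "OB", t100), noise,
                                        fs)$sta))
  a400 <- max(abs(spikeTriggeredAverage(SpikeUnit("b", "OB", t400), noise,
                                        fs)$sta))
  expect_equal(a100 / a400, 2, tolerance = 0.6)
  # gamma-locked unit has higher STA gamma power than an unlocked one
  rec <- simulateLFP(list(oscSpec("OB", "gamma", 60, 20, id = "g")), 120,
                     fs, noise = list(alpha = 1, sigma = 2), seed = 20)
  rec <- simulateSpikes(rec, list(
    unitSpec("OB", 5, "gamma", kappa = 2, unit_id = "locked"),
    unitSpec("OB", 5, "gamma", kappa = 0, unit_id = "unlocked")),
    seed = 21)
  x2 <- lfpSignal(rec, "OB")
  p_locked <- spikeTriggeredAverage(spikeUnits(rec)[[1]], x2, fs,
                                    band = "gamma")$sta_band_power
  p_unlocked <- spikeTriggeredAverage(spikeUnits(rec)[[2]], x2, fs,
                                      band = "gamma")$sta_band_power
  expect_gt(p_locked, p_unlocked)
})
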