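# Synthetic LFP, spikes and cohort generator: planted structure and
# determinism.

test_that("a noiseless oscillator concentrates its power in band", {
  fs <- 1000
  rec <- simulateLFP(list(oscSpec("OB", "theta", 8, 1,
                                  phase_diffusion = 0)),
                     10, fs, noise = NULL, seed = 1, regions = "OB")
  p <- welchPSD(lfpSignal(rec, "OB"), fs)
  df <- diff(p$freqs_hz)[1]
  total <- sum(p$psd) * df
  in_theta <- .bandIntegral(p$freqs_hz, p$psd, 3, 12)
  expect_gt(in_theta / total, 0.99)
  expect_error(simulateLFP(list(oscSpec("OB", "gamma", 94, 1)), 10,
                           fs_hz = 180), "Nyquist")
})

test_that("shared-source regions are near-coherent without noise", {
  fs <- 1000
  oscs <- list(
    oscSpec("OB", "gamma", 60, 1, id = "a", shared_source_id = "s"),
    oscSpec("aPC", "gamma", 60, 1, id = "b", shared_source_id = "s"))
  rec <- simulateLFP(oscs, 30, fs, noise = list(alpha = 1, sigma = 1e-4),
                     seed = 2)
  co <- bandCoherence(lfpSignal(rec, "OB"), lfpSignal(rec, "aPC"), fs)
  expect_gt(co$band_means[["gamma"]], 0.99)
})

test_that("1/f noise has the right spectral slope and is stationary", {
  fs <- 1000
  slopes <- vapply(1:10, function(s) {
    rec <- simulateLFP(list(), 100, fs, noise = list(alpha = 1, sigma = 1),
                       seed = 200 + s, regions = "OB")
    p <- welchPSD(lfpSignal(rec, "OB"), fs, segment_s = 4)
    sel <- p$freqs_hz >= 2 & p$freqs_hz <= 100
    coef(lm(log10(p$psd[sel]) ~ log10(p$freqs_hz[sel])))[2]
  }, numeric(1))
  expect_lt(abs(mean(slopes) + 1), 0.15)
  # variance stable across thirds of the recording
  rec <- simulateLFP(list(), 90, fs, noise = list(alpha = 1, sigma = 5),
                     seed = 3, regions = "OB")
  x <- lfpSignal(rec, "OB")
  v <- vapply(0:2, function(k) var(x[(k * 30000 + 1):((k + 1) * 30000)]),
              numeric(1))
  expect_lt(max(abs(v / mean(v) - 1)), 0.10)
})

test_that("thinning preserves the mean rate for every kappa", {
  fs <- 1000
  rec <- simulateLFP(list(oscSpec("OB", "theta", 8, 50, id = "t")), 100,
                     fs, noise = list(alpha = 1, sigma = 1), seed = 4,
                     regions = "OB")
  for (kappa in c(0, 2)) {
    counts <- vapply(1:20, function(s) {
      r <- simulateSpikes(rec, list(unitSpec("OB", 5, "theta",
                                             kappa = kappa)),
                          seed = 300 + s)
      length(spikeTimes(spikeUnits(r)[[1]]))
    }, numeric(1))
    # E[n] = r0 * duration = 500; SE of the mean of 20 Poisson counts
    se <- sqrt(500 / 20)
    expect_lt(abs(mean(counts) - 500), 3 * se)
  }
  # strong locking concentrates phases at mu
  r <- simulateSpikes(rec, list(unitSpec("OB", 10, "theta", kappa = 50,
                                         mu = 0.7)), seed = 5)
  pl <- spikePhaseLocking(spikeUnits(r)[[1]], lfpSignal(r, "OB"), fs,
                          "theta")
  expect_gt(pl$n_spikes, 500)
  expect_equal(pl$preferred_phase, 0.7, tolerance = 0.1)
  expect_error(unitSpec("OB", 5, "theta", kappa = -1), "kappa")
})

test_that("cohorts are bitwise reproducible and carry their ground truth", {
  sp <- cohortSpec(n_per_group = 1, duration_s = 30, seed = 7,
                   n_epochs_per_condition = 5)
  c1 <- simulateCohort(sp)
  c2 <- simulateCohort(sp)
  expect_identical(lfpMatrix(c1$subjects[[1]]$recording),
                   lfpMatrix(c2$subjects[[1]]$recording))
  expect_identical(spikeTimes(spikeUnits(c1$subjects[[2]]$recording)[[1]]),
                   spikeTimes(spikeUnits(c2$subjects[[2]]$recording)[[1]]))
  expect_identical(eventData(c1$subjects[[1]]$events),
                   eventData(c2$subjects[[1]]$events))
  gt <- c1$ground_truth
  expect_named(gt$subjects, names(c1$subjects))
  expect_equal(gt$subjects[[1]]$units[[1]]$kappa,
               .cohortCalib$kappa_gamma[["control"]])
  expect_s4_class(c1$subjects[[1]]$recording, "Recording")
})

test_that("the lesion group doubles firing rate by construction", {
  sp <- cohortSpec(n_per_group = 3, duration_s = 60, seed = 8)
  sim <- simulateCohort(sp)
  rate <- function(subj) mean(meanRate(subj$recording))
  groups <- vapply(sim$subjects, function(s)
    groupLabel(s$recording), character(1))
  r_ctrl <- mean(vapply(sim$subjects[groups == "control"], rate,
                        numeric(1)))
  r_les <- mean(vapply(sim$subjects[groups == "lesion"], rate, numeric(1)))
  expect_equal(r_les / r_ctrl, 2, tolerance = 0.15)
})

test_that("the planted novelty effect raises OB theta power in novel epochs", {
  sim <- simulateCohort(cohortSpec(n_per_group = 2, duration_s = 120,
                                   seed = 9, effect_d = 2))
  cfg <- pipelineConfig()
  diffs <- vapply(sim$subjects, function(s) {
    tr <- buildTrialFeatures(s$recording, s$events, "OB_theta_db", cfg)
    mean(tr$OB_theta_db[tr$condition == "novel"]) -
      mean(tr$OB_theta_db[tr$condition == "familiar"])
  }, numeric(1))
  expect_true(all(diffs > 0))
})
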