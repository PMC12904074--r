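# Amplitude matrix, co-participation features, ICA barcodes and scores.

# small synthetic amplitude matrix with known structure
fakeAmplitudeMatrix <- function(A_raw, channels, fs = 4) {
  sds <- apply(A_raw, 1, sd)
  structure(list(channels = channels, A_std = A_raw / sds, A_raw = A_raw,
                 sds = sds, fs_hz = fs), class = "AmplitudeMatrix")
}

test_that("amplitude matrix standardizes channels region-major", {
  fs <- 1000
  rec <- simulateLFP(list(oscSpec("OB", "theta", 7, 30, id = "a"),
                          oscSpec("aPC", "theta", 7, 30, id = "b")),
                     30, fs, noise = list(alpha = 1, sigma = 5), seed = 50,
                     regions = c("OB", "aPC"))
  sel <- lapply(setNames(c("OB", "aPC"), c("OB", "aPC")), function(r)
    selectIMFs(maskedEMD(lfpSignal(rec, r), fs, region = r)))
  M <- amplitudeMatrix(sel)
  expect_identical(M$channels,
                   c("OB.theta", "OB.beta", "OB.gamma",
                     "aPC.theta", "aPC.beta", "aPC.gamma"))
  expect_equal(unname(apply(M$A_std, 1, sd)), rep(1, 6), tolerance = 1e-9)
  expect_true(all(M$A_raw >= 0))
  # standardization constants round-trip to machine precision
  expect_equal(M$A_std * M$sds, M$A_raw, tolerance = 1e-12)
})

test_that("co-participation vectorizes the outer product upper triangle", {
  A <- rbind(rep(1, 8), rep(2, 8))   # constant envelopes over 2 windows
  M <- fakeAmplitudeMatrix(A + cbind(matrix(0, 2, 4),
                                     matrix(0.001, 2, 4)),
                           c("OB.theta", "OB.gamma"), fs = 16)
  cp <- coparticipation(M, window_s = 0.25, use_std = FALSE)
  expect_equal(nrow(cp$F), 2)
  expect_equal(cp$feature_index$name,
               c("OB.theta*OB.theta", "OB.theta*OB.gamma",
                 "OB.gamma*OB.gamma"))
  # v = (1, 2) -> features (1, 2, 4)
  expect_equal(unname(cp$F[1, ]), c(1, 2, 4), tolerance = 1e-2)
  # zero window -> zero feature row
  A0 <- cbind(matrix(1, 2, 4), matrix(0, 2, 4))
  M0 <- fakeAmplitudeMatrix(A0, c("OB.theta", "OB.gamma"), fs = 16)
  cp0 <- coparticipation(M0, window_s = 0.25, use_std = FALSE)
  expect_equal(unname(cp0$F[2, ]), c(0, 0, 0))
  # window-count conservation
  set.seed(51)
  M2 <- fakeAmplitudeMatrix(matrix(abs(rnorm(3 * 4100)), 3),
                            c("OB.theta", "OB.beta", "OB.gamma"), fs = 4)
  expect_equal(nrow(coparticipation(M2, 0.25)$F), floor(1025 / 0.25))
})

test_that("fitBarcodes is deterministic, unit-norm, sign-fixed and guarded", {
  set.seed(52)
  S <- cbind(runif(600)^2, rexp(600), rbinom(600, 1, 0.3))
  mix <- matrix(rnorm(18), 6, 3)
  # co-participation matrix from a synthetic non-negative envelope matrix
  M <- fakeAmplitudeMatrix(t(abs(S %*% t(mix))) + 0.05,
                           c("OB.theta", "OB.beta", "OB.gamma",
                             "aPC.theta", "aPC.beta", "aPC.gamma"), fs = 4)
  F_std <- coparticipation(M, window_s = 0.25, use_std = TRUE)
  m1 <- fitBarcodes(F_std, n_barcodes = 3, seed = 9)
  m2 <- fitBarcodes(F_std, n_barcodes = 3, seed = 9)
  expect_identical(barcodeWeights(m1), barcodeWeights(m2))
  expect_equal(unname(sqrt(rowSums(barcodeWeights(m1)^2))), rep(1, 3))
  for (k in 1:3) {
    w <- barcodeWeights(m1)[k, ]
    expect_gt(w[which.max(abs(w))], 0)
  }
  # permuting window order leaves weights unchanged up to order/sign
  F_perm <- F_std
  set.seed(53)
  F_perm$F <- F_perm$F[sample(nrow(F_perm$F)), ]
  m3 <- fitBarcodes(F_perm, n_barcodes = 3, seed = 9)
  expect_gt(min(matchedCosines(barcodeWeights(m3), barcodeWeights(m1))),
            0.999)
  expect_error(fitBarcodes(F_std, n_barcodes = 200, seed = 1),
               "at least")
  expect_error(fitBarcodes(coparticipation(M, 0.25, use_std = FALSE), 3),
               "standardized")
})

test_that("barcode strength is the dot product with raw features", {
  set.seed(54)
  M <- fakeAmplitudeMatrix(matrix(abs(rnorm(3 * 800)) + 0.2, 3),
                           c("OB.theta", "OB.beta", "OB.gamma"), fs = 4)
  F_std <- coparticipation(M, 0.25, use_std = TRUE)
  F_raw <- coparticipation(M, 0.25, use_std = FALSE)
  model <- fitBarcodes(F_std, n_barcodes = 2, seed = 4)
  st <- barcodeStrength(model, F_raw)
  expect_equal(st$strength, F_raw$F %*% t(barcodeSignatures(model)),
               ignore_attr = TRUE)
  stu <- barcodeStrength(model, F_raw, use = "unmixing")
  expect_equal(stu$strength, F_raw$F %*% t(barcodeWeights(model)),
               ignore_attr = TRUE)
  # one-hot barcode vector picks out a single raw feature
  model@W <- matrix(0, 1, ncol(F_raw$F))
  model@W[1, 2] <- 1
  model@signatures <- model@W
  st1 <- barcodeStrength(model, F_raw)
  expect_equal(unname(st1$strength[, 1]), unname(F_raw$F[, 2]))
  # zero recording -> zero strengths
  F0 <- F_raw
  F0$F[] <- 0
  expect_true(all(barcodeStrength(model, F0)$strength == 0))
})

test_that("planted patterns co-modulate loaded channels and are recovered", {
  fs <- 1000
  oscs <- unlist(lapply(c("OB", "aPC", "LEC"), function(r) list(
    oscSpec(r, "theta", 7, 20, id = paste0(r, ".theta"), phase_diffusion = 4),
    oscSpec(r, "beta", 25, 12, id = paste0(r, ".beta"), phase_diffusion = 20),
    oscSpec(r, "gamma", 60, 12, id = paste0(r, ".gamma"),
            phase_diffusion = 120))), recursive = FALSE)
  rec <- simulateLFP(oscs, 120, fs, noise = list(alpha = 1, sigma = 3),
                     seed = 55, regions = c("OB", "aPC", "LEC"))
  epochs_on <- data.frame(start_s = c(10, 50, 90), end_s = c(30, 70, 110))
  pat <- list(name = "p1",
              loadings = c(OB.gamma = 4, aPC.gamma = 4),
              epochs = epochs_on)
  pl <- plantBarcodePatterns(rec, list(pat), seed = 56)
  on_idx <- rep(FALSE, nSamples(rec))
  for (r in seq_len(nrow(epochs_on)))
    on_idx[(epochs_on$start_s[r] * fs):(epochs_on$end_s[r] * fs)] <- TRUE
  env <- function(r0, x) bandpassAnalytic(lfpSignal(x, r0), fs,
                                          "gamma")$amplitude
  e1 <- env("OB", pl$recording); e2 <- env("aPC", pl$recording)
  # shared lognormal latent against independent background envelopes gives
  # within-epoch correlation of 0.75-0.84 across seeds at loading 4
  expect_gt(cor(e1[on_idx], e2[on_idx]), 0.7)
  expect_lt(abs(cor(e1[!on_idx], e2[!on_idx])), 0.25)
  # zero-loading pattern leaves the recording untouched bitwise
  pl0 <- plantBarcodePatterns(rec, list(list(
    name = "null", loadings = c(OB.gamma = 0), epochs = epochs_on)),
    seed = 57)
  expect_identical(lfpMatrix(pl0$recording), lfpMatrix(rec))
  expect_error(plantBarcodePatterns(rec, list(list(
    name = "bad", loadings = c(HPC.gamma = 1), epochs = epochs_on))),
    "unknown channel")
  # matched barcode strength is higher inside activation epochs
  ba <- barcodeAnalysis(pl$recording, pipelineConfig(n_barcodes = 6),
                        seed = 58)
  w_on <- windowsIn(ba$F_std$times_s, epochs_on)
  sig <- contrastSignature(ba$F_std, w_on)
  cs <- abs(barcodeSignatures(ba$model) %*% sig)
  k <- which.max(cs)
  expect_gt(cs[k], 0.9)
  pv <- stats::wilcox.test(ba$strengths$strength[w_on, k],
                           ba$strengths$strength[!w_on, k],
                           alternative = "greater")$p.value
  expect_lt(pv, 0.01)
})

test_that("barcode scores rank condition separation as ROC areas", {
  st <- structure(list(times_s = seq(0.125, 10, by = 0.25),
                       strength = cbind(a = 1:40, b = rep(c(1, 2), 20)),
                       window_s = 0.25), class = "StrengthSeries")
  ev <- EventTable(data.frame(
    epoch_id = paste0("e", 1:4),
    label = paste0("e", 1:4),
    start_s = c(0, 2.5, 5, 7.5), end_s = c(2.5, 5, 7.5, 10),
    condition = c("familiar", "familiar", "novel", "novel"),
    stringsAsFactors = FALSE))
  sc <- barcodeScore(st, ev, "novel")
  expect_equal(unname(sc["a"]), 1)       # strictly higher in novel windows
  expect_equal(unname(sc["b"]), 0.5, tolerance = 0.05)
  ev1 <- EventTable(eventData(ev)[1:2, ])
  expect_error(barcodeScore(st, ev1, "novel"), "2 epochs")
})

test_that("scaling the LFP leaves barcodes invariant and scales strengths", {
  fs <- 500
  set.seed(59)
  rec <- simulateLFP(list(oscSpec("OB", "theta", 7, 20, id = "t"),
                          oscSpec("OB", "gamma", 60, 10, id = "g")),
                     60, fs, noise = list(alpha = 1, sigma = 3), seed = 59,
                     regions = "OB")
  cfg <- pipelineConfig(n_barcodes = 3)
  ba1 <- barcodeAnalysis(rec, cfg, seed = 60)
  rec2 <- rec
  rec2@lfp <- rec2@lfp * 3
  ba2 <- barcodeAnalysis(rec2, cfg, seed = 60)
  expect_gt(min(matchedCosines(barcodeWeights(ba2$model),
                               barcodeWeights(ba1$model))), 0.98)
  # strengths of matched components scale with the squared signal scale
  C <- abs(barcodeWeights(ba2$model) %*% t(barcodeWeights(ba1$model)))
  perm <- clue::solve_LSAP(C, maximum = TRUE)
  s1 <- apply(abs(ba1$strengths$strength), 2, mean)
  s2 <- apply(abs(ba2$strengths$strength), 2, mean)
  ratios <- s2 / s1[as.integer(perm)]
  expect_equal(unname(ratios), rep(9, 3), tolerance = 0.15)
})
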