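# Trial features, SVM decoding, chance intervals and forecasting.

test_that("trial tables have one row per epoch and planted effects show", {
  sim <- simulateCohort(cohortSpec(n_per_group = 1, duration_s = 60,
                                   seed = 61, n_epochs_per_condition = 8,
                                   effect_d = 2))
  s <- sim$subjects[[1]]
  tr <- buildTrialFeatures(s$recording, s$events,
                           c("OB_theta_db", "LEC_theta_db"),
                           pipelineConfig())
  expect_equal(nrow(tr), 16)
  expect_named(tr, c("subject_id", "group", "trial_id", "condition",
                     "OB_theta_db", "LEC_theta_db"))
  expect_gt(mean(tr$OB_theta_db[tr$condition == "novel"]),
            mean(tr$OB_theta_db[tr$condition == "familiar"]))
  # barcode features demand a fitted model
  expect_error(buildTrialFeatures(s$recording, s$events, "barcode_1",
                                  pipelineConfig()),
               "requires a fitted barcode model")
  expect_error(buildTrialFeatures(s$recording, s$events, "nonsense",
                                  pipelineConfig()),
               "unknown feature")
})

test_that("decoding is deterministic, leakage-free and balanced", {
  trials <- simulateTrialTable(n_per_group = 4, trials_per_condition = 10,
                               d = 1, seed = 62)
  r1 <- svmDecode(trials, n_iter = 20, seed = 5)
  r2 <- svmDecode(trials, n_iter = 20, seed = 5)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_equal(length(r1$accuracies), 20)
  expect_true(all(r1$accuracies >= 0 & r1$accuracies <= 1))
  # structural check of the split rule: every subject entirely in train
  # or test, and training balance is exact after down-sampling
  subj <- trials$subject_id
  set.seed(5)
  for (i in 1:5) {
    train_subj <- unlist(lapply(c("control", "lesion"), function(g) {
      sg <- unique(subj[trials$group == g])
      sample(sg, round(0.8 * length(sg)))
    }))
    test_rows <- which(!subj %in% train_subj)
    expect_length(intersect(subj[test_rows], train_subj), 0)
  }
})

test_that("separable features decode near-perfectly; nulls sit at chance", {
  sep <- simulateTrialTable(n_per_group = 5, trials_per_condition = 15,
                            d = 4, subject_sd = 0.2, seed = 63)
  r <- svmDecode(sep, n_iter = 50, seed = 6)
  expect_gt(r$mean_accuracy, 0.95)
  nul <- simulateTrialTable(n_per_group = 5, trials_per_condition = 15,
                            d = 0, seed = 64)
  rn <- svmDecode(nul, n_iter = 50, n_shuffles = 25, seed = 7)
  expect_false(rn$significant)
  expect_equal(mean(rn$chance_interval), 0.5)
  expect_gt(rn$chance_interval[2], 0.5)
})

test_that("chance intervals contain 0.5 and narrow with more trials", {
  widths <- vapply(c(6, 24), function(ntr) {
    trials <- simulateTrialTable(n_per_group = 4,
                                 trials_per_condition = ntr, d = 0,
                                 seed = 65)
    ci <- chanceInterval(trials, n_iter = 15, n_shuffles = 15, seed = 8)
    expect_lt(ci[1], 0.5)
    expect_gt(ci[2], 0.5)
    diff(ci)
  }, numeric(1))
  expect_lt(widths[2], widths[1])
  # within-subject permutation preserves per-subject class counts
  trials <- simulateTrialTable(n_per_group = 3, trials_per_condition = 7,
                               d = 0, seed = 66)
  set.seed(9)
  for (rows in split(seq_len(nrow(trials)), trials$subject_id)) {
    shuffled <- sample(trials$condition[rows])
    expect_equal(as.vector(table(shuffled)),
                 as.vector(table(trials$condition[rows])))
  }
})

test_that("forecasting separable outcomes reaches AUC 1 and nulls stay at 0.5", {
  set.seed(67)
  n <- 40
  early <- data.frame(subject_id = sprintf("s%02d", 1:n),
                      gamma_coh = c(rnorm(n / 2, 0.6, 0.03),
                                    rnorm(n / 2, 0.4, 0.03)),
                      noise = rnorm(n))
  outcome <- rep(c(FALSE, TRUE), each = n / 2)
  f <- forecastOutcome(early, outcome, seed = 10)
  expect_gte(f$auc, 0.98)
  expect_equal(sum(diag(f$confusion_test)), length(f$split$test))
  # numeric outcomes binarize as di < threshold
  di <- ifelse(outcome, -20, 30) + rnorm(n, sd = 1)
  f2 <- forecastOutcome(early, di, threshold = 0, seed = 10)
  expect_gte(f2$auc, 0.98)
  # label-independent features: AUC near 0.5 on average
  aucs <- vapply(1:10, function(s) {
    set.seed(700 + s)
    early_n <- data.frame(subject_id = sprintf("s%02d", 1:n),
                          f1 = rnorm(n), f2 = rnorm(n))
    forecastOutcome(early_n, sample(outcome), seed = s)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
  expect_error(forecastOutcome(early[1:6, ], outcome[c(1:3, 21:23)]),
               "4 subjects")
})

test_that("forecast AUC agrees with the pROC oracle", {
  set.seed(68)
  pos <- runif(15); neg <- runif(12) - 0.2
  own <- lfpbarcode:::.aucRank(pos, neg)
  oracle <- as.numeric(pROC::auc(
    response = c(rep(1, 15), rep(0, 12)),
    predictor = c(pos, neg), direction = "<", quiet = TRUE))
  expect_equal(own, oracle, tolerance = 1e-12)
})
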