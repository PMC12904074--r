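#' Build a trial feature table from a recording and its events
#'
#' One row per familiar/novel behavioral epoch with the requested neural
#' features, joined deterministically on `epoch_id`. Feature names follow
#' the conventions:
#' * `"<region>_<band>_db"` — epoch band power in dB ([bandPowerDb()], at
#'   the fixed `epoch_segment_s` resolution);
#' * `"<regionA>_<regionB>_<band>_coh"` — epoch band coherence (short
#'   epochs give few Welch segments, so these are biased features for
#'   decoding, not coherence estimates — the high-bias warning is
#'   suppressed here);
#' * `"barcode_<k>"` — mean strength of barcode k over the epoch (requires
#'   `strengths` from a fitted model).
#'
#' @param rec a [Recording-class].
#' @param events an [EventTable-class]; only `familiar`/`novel` epochs are
#'   used.
#' @param features character vector of feature names.
#' @param cfg a [PipelineConfig-class].
#' @param epoch_segment_s fixed Welch segment length for epoch features,
#'   seconds (default 0.5). A fixed segment keeps the spectral resolution --
#'   and hence any leakage bias -- identical across epochs of different
#'   duration, so epoch length cannot masquerade as a power difference.
#' @param strengths optional `"StrengthSeries"` for barcode features.
#' @return A data.frame (`subject_id`, `group`, `trial_id`, `condition`,
#'   one column per feature).
#' @export
buildTrialFeatures <- function(rec, events, features,
                               cfg = pipelineConfig(),
                               epoch_segment_s = 0.5, strengths = NULL) {
  stopifnot(is(rec, "Recording"), is(events, "EventTable"))
  ev <- events@events
  ev <- ev[ev$condition %in% c("familiar", "novel"), , drop = FALSE]
  if (!nrow(ev)) stop("no familiar/novel epochs in the event table")
  fs <- rec@fs_hz
  out <- data.frame(subject_id = rec@subject_id, group = rec@group,
                    trial_id = ev$epoch_id, condition = ev$condition,
                    stringsAsFactors = FALSE)
  for (f in features) {
    vals <- numeric(nrow(ev))
    if (grepl("^barcode_\\d+$", f)) {
      if (is.null(strengths))
        stop("feature '", f, "' requires a fitted barcode model ",
             "(pass its strength series)")
      k <- as.integer(sub("^barcode_", "", f))
      if (k > ncol(strengths$strength))
        stop("feature '", f, "': model has only ",
             ncol(strengths$strength), " barcodes")
      for (r in seq_len(nrow(ev))) {
        idx <- strengths$times_s >= ev$start_s[r] &
               strengths$times_s < ev$end_s[r]
        if (!any(idx))
          stop("feature '", f, "' missing for epoch '", ev$epoch_id[r],
               "': no strength windows inside the epoch")
        vals[r] <- mean(strengths$strength[idx, k])
      }
    } else if (grepl("_db$", f)) {
      parts <- strsplit(sub("_db$", "", f), "_")[[1L]]
      if (length(parts) != 2)
        stop("cannot parse feature name '", f, "'")
      for (r in seq_len(nrow(ev))) {
        sl <- sliceEpoch(rec, ev$start_s[r], ev$end_s[r])
        seg <- min(epoch_segment_s, floor(nSamples(sl) / 2) / fs)
        vals[r] <- bandPowerDb(lfpSignal(sl, parts[1L]), fs, parts[2L],
                               segment_s = seg, overlap = cfg@psd_overlap,
                               bands = cfg@bands)$power_db
      }
    } else if (grepl("_coh$", f)) {
      parts <- strsplit(sub("_coh$", "", f), "_")[[1L]]
      if (length(parts) != 3)
        stop("cannot parse feature name '", f, "'")
      for (r in seq_len(nrow(ev))) {
        sl <- sliceEpoch(rec, ev$start_s[r], ev$end_s[r])
        seg <- min(epoch_segment_s / 2, floor(nSamples(sl) / 4) / fs)
        co <- suppressWarnings(bandCoherence(
          lfpSignal(sl, parts[1L]), lfpSignal(sl, parts[2L]), fs,
          bands = cfg@bands, segment_s = seg, overlap = cfg@psd_overlap))
        vals[r] <- co$band_means[[parts[3L]]]
      }
    } else stop("unknown feature pattern: '", f, "'")
    out[[f]] <- vals
  }
  out
}

#' Simulate a trial feature table with a planted condition effect
#'
#' Lightweight generative model of the decoding problem: each subject gets a
#' Gaussian random intercept (between-animal variability), the first feature
#' shifts by `d` within-trial standard deviations in novel trials, and the
#' remaining features are condition-independent noise. `d = 0` is the null
#' world for chance calibration.
#'
#' @param n_per_group subjects per group.
#' @param trials_per_condition trials of each condition per subject.
#' @param d planted effect size (within-class SDs) on the first feature.
#' @param n_features number of features (default 2).
#' @param subject_sd SD of the subject random intercept (default 0.5).
#' @param groups group labels (default both).
#' @param seed integer seed.
#' @return A trial table as from [buildTrialFeatures()].
#' @export
simulateTrialTable <- function(n_per_group = 7, trials_per_condition = 20,
                               d = 0, n_features = 2, subject_sd = 0.5,
                               groups = c("control", "lesion"), seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in groups) for (s in seq_len(n_per_group)) {
    sid <- sprintf("%s_%02d", g, s)
    b <- rnorm(n_features, sd = subject_sd)
    cond <- rep(c("familiar", "novel"), each = trials_per_condition)
    X <- matrix(rnorm(length(cond) * n_features), ncol = n_features)
    X <- sweep(X, 2L, b, "+")
    X[cond == "novel", 1L] <- X[cond == "novel", 1L] + d
    df <- data.frame(subject_id = sid, group = g,
                     trial_id = sprintf("%s_t%03d", sid, seq_along(cond)),
                     condition = cond, stringsAsFactors = FALSE)
    colnames(X) <- paste0("feature_", seq_len(n_features))
    rows[[length(rows) + 1L]] <- cbind(df, X)
  }
  do.call(rbind, rows)
}

.trialMeta <- c("subject_id", "group", "trial_id", "condition")

.checkTrials <- function(trials, features) {
  stopifnot(is.data.frame(trials))
  if (!all(.trialMeta %in% names(trials)))
    stop("trial table needs columns: ", paste(.trialMeta, collapse = ", "))
  if (is.null(features))
    features <- setdiff(names(trials), .trialMeta)
  if (!length(features)) stop("no feature columns")
  X <- as.matrix(trials[, features, drop = FALSE])
  if (anyNA(X)) stop("missing feature values in the trial table")
  cls <- unique(trials$condition)
  if (length(cls) != 2) stop("condition must have exactly 2 levels")
  list(X = X, features = features)
}

## one full decoding run: subject-wise stratified split, training-class
## balancing, train-fold z-scoring, linear SVM (C = 1), pooled trial-level
## test accuracy. Assumes a valid RNG state; returns the accuracy vector.
.decodeCore <- function(X, cond, subj, grp, train_frac, n_iter, cost = 1) {
  subjects <- unique(subj)
  subj_group <- grp[match(subjects, subj)]
  subj_rows <- split(seq_along(subj), subj)[subjects]
  lev <- sort(unique(cond))
  acc <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    for (retry in 1:100) {
      train_subj <- unlist(lapply(unique(subj_group), function(g) {
        sg <- subjects[subj_group == g]
        n_tr <- max(1L, min(length(sg) - 1L, round(train_frac * length(sg))))
        sample(sg, n_tr)
      }))
      test_rows <- unlist(subj_rows[setdiff(subjects, train_subj)],
                          use.names = FALSE)
      if (length(unique(cond[test_rows])) == 2L) break
      if (retry == 100)
        stop("could not find a split with both classes in the test set")
    }
    train_rows <- unlist(subj_rows[train_subj], use.names = FALSE)
    ## balance training classes by random down-sampling
    i1 <- train_rows[cond[train_rows] == lev[1L]]
    i2 <- train_rows[cond[train_rows] == lev[2L]]
    m <- min(length(i1), length(i2))
    if (m < 2) stop("training split has fewer than 2 trials in a class")
    if (length(i1) > m) i1 <- sample(i1, m)
    if (length(i2) > m) i2 <- sample(i2, m)
    train_rows <- c(i1, i2)
    ## z-score on training statistics
    mu <- colMeans(X[train_rows, , drop = FALSE])
    sg <- apply(X[train_rows, , drop = FALSE], 2L, sd)
    sg[sg == 0] <- 1
    Xtr <- sweep(sweep(X[train_rows, , drop = FALSE], 2L, mu), 2L, sg, "/")
    Xte <- sweep(sweep(X[test_rows, , drop = FALSE], 2L, mu), 2L, sg, "/")
    fit <- e1071::svm(Xtr, factor(cond[train_rows], levels = lev),
                      kernel = "linear", cost = cost, scale = FALSE,
                      fitted = FALSE)
    w <- crossprod(fit$coefs, fit$SV)
    dec <- as.vector(Xte %*% t(w)) - fit$rho
    pred <- fit$levels[2L - (dec > 0)]
    acc[it] <- mean(pred == cond[test_rows])
  }
  acc
}

#' Linear-SVM population decoding with a shuffle-calibrated chance interval
#'
#' Decodes familiar-vs-novel trials with a linear support vector machine
#' (C = 1). Each of `n_iter` cross-validation iterations: subjects are split
#' 80/20 within each group (every animal's trials land entirely in train or
#' test — no leakage), training classes are balanced by random
#' down-sampling, features are z-scored on training statistics, and accuracy
#' is pooled over held-out trials. With `n_shuffles > 0` the chance interval
#' `0.5 +/- 2 SD` of null mean accuracies (labels permuted within subject,
#' preserving each animal's class counts) is computed and the result flagged
#' significant when the mean accuracy falls outside it.
#'
#' @param trials trial table ([buildTrialFeatures()] or
#'   [simulateTrialTable()]).
#' @param features feature columns (default: all non-metadata columns).
#' @param train_frac fraction of subjects in training (default 0.8).
#' @param n_iter cross-validation iterations (default 500).
#' @param n_shuffles label shuffles for the chance interval (0 = skip).
#' @param seed integer seed.
#' @param cost SVM regularization constant (default 1).
#' @return An object of class `"DecodingResult"`: list with `accuracies`,
#'   `mean_accuracy`, `chance_interval`, `null_means`, `significant`,
#'   `config`.
#' @export
svmDecode <- function(trials, features = NULL, train_frac = 0.8,
                      n_iter = 500, n_shuffles = 0, seed = 1, cost = 1) {
  ck <- .checkTrials(trials, features)
  if (length(unique(trials$subject_id)) < 2)
    stop("need at least 2 subjects")
  set.seed(seed)
  acc <- .decodeCore(ck$X, trials$condition, trials$subject_id,
                     trials$group, train_frac, n_iter, cost)
  res <- structure(
    list(accuracies = acc, mean_accuracy = mean(acc),
         chance_interval = NULL, null_means = NULL, significant = NA,
         config = list(train_frac = train_frac, n_iter = n_iter,
                       n_shuffles = n_shuffles, seed = seed, cost = cost,
                       features = ck$features)),
    class = "DecodingResult")
  if (n_shuffles > 0) {
    ci <- chanceInterval(trials, features = ck$features,
                         train_frac = train_frac, n_iter = n_iter,
                         n_shuffles = n_shuffles,
                         seed = .subSeed(seed, 101L), cost = cost)
    res$chance_interval <- ci
    res$null_means <- attr(ci, "null_means")
    res$significant <- res$mean_accuracy < ci[1L] ||
      res$mean_accuracy > ci[2L]
  }
  res
}

#' @export
print.DecodingResult <- function(x, ...) {
  cat(sprintf("SVM decoding: mean accuracy %.3f over %d iterations\n",
              x$mean_accuracy, length(x$accuracies)))
  if (!is.null(x$chance_interval))
    cat(sprintf("  chance interval [%.3f, %.3f] (%d shuffles): %s\n",
                x$chance_interval[1L], x$chance_interval[2L],
                x$config$n_shuffles,
                if (isTRUE(x$significant)) "SIGNIFICANT" else
                  "not significant"))
  invisible(x)
}

#' Shuffle-derived chance interval for decoding accuracy
#'
#' Permutes condition labels within each subject (preserving every animal's
#' class counts), reruns the full decoding procedure per shuffle, and
#' returns `0.5 +/- 2 SD` of the null mean accuracies. The interval is
#' centered at the theoretical chance level by construction.
#'
#' @inheritParams svmDecode
#' @return Numeric `c(lo, hi)` with the null means as attribute
#'   `"null_means"`.
#' @export
chanceInterval <- function(trials, features = NULL, train_frac = 0.8,
                           n_iter = 500, n_shuffles = 100, seed = 1,
                           cost = 1) {
  ck <- .checkTrials(trials, features)
  set.seed(seed)
  subj_rows <- split(seq_len(nrow(trials)), trials$subject_id)
  null_means <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    cond <- trials$condition
    for (rows in subj_rows)
      cond[rows] <- sample(cond[rows])
    null_means[s] <- mean(.decodeCore(ck$X, cond, trials$subject_id,
                                      trials$group, train_frac, n_iter,
                                      cost))
  }
  s2 <- sd(null_means)
  structure(c(0.5 - 2 * s2, 0.5 + 2 * s2), null_means = null_means)
}

#' Forecast a later binary outcome from early features
#'
#' Trains a bagged tree ensemble (random forest, 500 trees) to predict a
#' later behavioral outcome (e.g. cognitive impairment, defined as a
#' discrimination index below 0) from features measured weeks earlier, using
#' a subject-level stratified 80/20 split. Reports the test AUC of the
#' out-of-split class probabilities, train/test confusion matrices at the
#' 0.5 probability threshold, and feature importances.
#'
#' @param early_features data.frame, one row per subject: `subject_id` plus
#'   numeric feature columns.
#' @param later_outcome logical/binary vector (TRUE = impaired), or numeric
#'   discrimination indices binarized as `di < threshold`.
#' @param threshold binarization threshold for numeric outcomes (default 0).
#' @param n_trees trees in the ensemble (default 500).
#' @param train_frac fraction of subjects used for training (default 0.8).
#' @param seed integer seed.
#' @return An object of class `"ForecastResult"`: list with `auc`,
#'   `confusion_train`, `confusion_test`, `importance`, `split` (subject
#'   ids), `test_scores`.
#' @export
forecastOutcome <- function(early_features, later_outcome, threshold = 0,
                            n_trees = 500, train_frac = 0.8, seed = 1) {
  stopifnot(is.data.frame(early_features),
            "subject_id" %in% names(early_features))
  if (is.numeric(later_outcome) && !all(later_outcome %in% c(0, 1)))
    later_outcome <- later_outcome < threshold
  y <- factor(ifelse(as.logical(later_outcome), "impaired", "intact"),
              levels = c("intact", "impaired"))
  if (length(y) != nrow(early_features))
    stop("one outcome per subject is required")
  if (min(table(y)) < 4)
    stop("need at least 4 subjects per outcome class")
  feat <- setdiff(names(early_features), c("subject_id", "group"))
  X <- as.matrix(early_features[, feat, drop = FALSE])
  set.seed(seed)
  ## stratified subject-level split
  test_idx <- unlist(lapply(levels(y), function(l) {
    i <- which(y == l)
    sample(i, max(1L, round((1 - train_frac) * length(i))))
  }))
  train_idx <- setdiff(seq_along(y), test_idx)
  rf <- randomForest::randomForest(X[train_idx, , drop = FALSE],
                                   y[train_idx], ntree = n_trees)
  p_tr <- predict(rf, X[train_idx, , drop = FALSE], type = "prob")[, "impaired"]
  p_te <- predict(rf, X[test_idx, , drop = FALSE], type = "prob")[, "impaired"]
  conf <- function(p, truth) {
    pred <- factor(ifelse(p >= 0.5, "impaired", "intact"),
                   levels = levels(y))
    table(truth = truth, predicted = pred)
  }
  pos <- p_te[y[test_idx] == "impaired"]
  neg <- p_te[y[test_idx] == "intact"]
  auc <- if (length(pos) && length(neg)) .aucRank(pos, neg) else NA_real_
  structure(list(auc = auc,
                 confusion_train = conf(p_tr, y[train_idx]),
                 confusion_test = conf(p_te, y[test_idx]),
                 importance = randomForest::importance(rf)[, 1L],
                 split = list(train = early_features$subject_id[train_idx],
                              test = early_features$subject_id[test_idx]),
                 test_scores = p_te),
            class = "ForecastResult")
}

#' @export
print.ForecastResult <- function(x, ...) {
  cat(sprintf("Forecast: test AUC %.3f (%d train / %d test subjects)\n",
              x$auc, length(x$split$train), length(x$split$test)))
  print(x$confusion_test)
  invisible(x)
}
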