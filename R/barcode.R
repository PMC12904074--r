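#' Standardized cross-regional amplitude matrix
#'
#' Stacks the band-assigned Hilbert amplitude envelopes of every region into
#' one matrix with channels ordered region-major (all bands of the first
#' region, then the second, ...). `A_std` divides each channel by its
#' standard deviation; the mean is deliberately not removed, since envelopes
#' are non-negative and the ICA step performs its own centering. The
#' standardization constants are kept so `A_std * sd` reproduces `A_raw` to
#' machine precision.
#'
#' @param selected named list (by region) of `"IMFSet"` objects that went
#'   through [selectIMFs()]; all regions must share `fs_hz` and length.
#' @return An object of class `"AmplitudeMatrix"`: list with `channels`
#'   (labels `region.band`), `A_std`, `A_raw` (`n_channels x n_samples`),
#'   `sds`, `fs_hz`.
#' @export
amplitudeMatrix <- function(selected) {
  stopifnot(length(selected) >= 1, !is.null(names(selected)))
  fs <- unique(vapply(selected, function(s) s$fs_hz, numeric(1)))
  if (length(fs) != 1) stop("all regions must share the sampling rate")
  lens <- vapply(selected, function(s)
    length(s$band_channels[[1L]]$envelope), integer(1))
  if (length(unique(lens)) != 1)
    stop("all regions must share the recording duration")
  rows <- list()
  for (reg in names(selected)) {
    ch <- selected[[reg]]$band_channels
    if (is.null(ch)) stop("region '", reg, "': run selectIMFs() first")
    for (b in names(ch))
      rows[[paste(reg, b, sep = ".")]] <- ch[[b]]$envelope
  }
  A_raw <- do.call(rbind, rows)
  sds <- apply(A_raw, 1L, sd)
  zero <- which(sds == 0)
  if (length(zero))
    stop("zero-variance amplitude channel: ",
         paste(names(rows)[zero], collapse = ", "))
  structure(list(channels = names(rows), A_std = A_raw / sds,
                 A_raw = A_raw, sds = sds, fs_hz = fs),
            class = "AmplitudeMatrix")
}

#' @export
print.AmplitudeMatrix <- function(x, ...) {
  cat(sprintf("AmplitudeMatrix: %d channels x %d samples @ %g Hz\n",
              nrow(x$A_raw), ncol(x$A_raw), x$fs_hz))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

## upper-triangle (including diagonal) feature index for n channels
.featureIndex <- function(channels) {
  n <- length(channels)
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]
  data.frame(i = unname(ij[, "row"]), j = unname(ij[, "col"]),
             name = paste(channels[ij[, "row"]], channels[ij[, "col"]],
                          sep = "*"),
             stringsAsFactors = FALSE)
}

#' Co-participation feature matrix
#'
#' Splits the amplitude matrix into non-overlapping windows (default 250 ms),
#' takes the window mean of every channel, forms the outer product of that
#' vector with itself, and keeps the upper triangle including the diagonal
#' (the outer product is symmetric; diagonal terms carry within-channel
#' power). One row per window, `n_channels * (n_channels + 1) / 2` features.
#'
#' @param M an `"AmplitudeMatrix"`.
#' @param window_s window length in seconds (default 0.25).
#' @param use_std use the standardized amplitudes (`TRUE`, for fitting) or
#'   the raw amplitudes (`FALSE`, for strength time series).
#' @return An object of class `"CoparticipationMatrix"`: list with `F`
#'   (`n_windows x n_features`), `feature_index`, `times_s` (window
#'   centers), `window_s`, `channels`, `use_std`.
#' @export
coparticipation <- function(M, window_s = 0.25, use_std = TRUE) {
  stopifnot(inherits(M, "AmplitudeMatrix"))
  A <- if (use_std) M$A_std else M$A_raw
  wlen <- round(window_s * M$fs_hz)
  n_win <- floor(ncol(A) / wlen)
  if (n_win < 1) stop("recording shorter than one window")
  fi <- .featureIndex(M$channels)
  FF <- matrix(NA_real_, n_win, nrow(fi))
  colnames(FF) <- fi$name
  for (w in seq_len(n_win)) {
    v <- rowMeans(A[, ((w - 1L) * wlen + 1L):(w * wlen), drop = FALSE])
    FF[w, ] <- v[fi$i] * v[fi$j]
  }
  structure(list(F = FF, feature_index = fi,
                 times_s = (seq_len(n_win) - 0.5) * wlen / M$fs_hz,
                 window_s = wlen / M$fs_hz, channels = M$channels,
                 use_std = use_std),
            class = "CoparticipationMatrix")
}

#' @export
print.CoparticipationMatrix <- function(x, ...) {
  cat(sprintf("Co-participation matrix: %d windows x %d features (%g-s windows, %s amplitudes)\n",
              nrow(x$F), ncol(x$F), x$window_s,
              if (x$use_std) "standardized" else "raw"))
  invisible(x)
}

#' Fit barcode weight vectors by ICA
#'
#' Centers the standardized co-participation features, whitens them by PCA to
#' `n_barcodes` dimensions, and runs fixed-point ICA (log-cosh contrast,
#' deflation) to obtain independent components. The unmixing rows mapped back
#' to feature space are the barcode weight vectors: unit-norm, with the sign
#' fixed so each row's largest-magnitude element is positive. The model also
#' keeps each component's feature-space signature (the unit-norm mixing
#' direction): the weight vector extracts the component, the signature is
#' the co-participation pattern it imprints, and the two coincide only when
#' components do not overlap in feature space. The fit is deterministic
#' given the seed (which only sets the orthogonal initialization of the ICA
#' rotation).
#'
#' @param F_std a `"CoparticipationMatrix"` built from standardized
#'   amplitudes.
#' @param n_barcodes number of barcodes (default 8).
#' @param seed integer seed for the ICA initialization.
#' @param maxit,tol fixed-point iteration limits.
#' @return A [BarcodeModel-class].
#' @export
fitBarcodes <- function(F_std, n_barcodes = 8, seed = 1, maxit = 200,
                        tol = 1e-6) {
  stopifnot(inherits(F_std, "CoparticipationMatrix"))
  if (!F_std$use_std)
    stop("fitBarcodes expects features built from standardized amplitudes")
  X <- F_std$F
  n_win <- nrow(X)
  if (n_win < 10 * n_barcodes)
    stop(sprintf("need at least %d windows to fit %d barcodes, got %d",
                 10 * n_barcodes, n_barcodes, n_win))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  rk <- qr(Xc)$rank
  if (n_barcodes > rk)
    stop(sprintf("n_barcodes (%d) exceeds the feature-matrix rank (%d)",
                 n_barcodes, rk))
  set.seed(seed)
  R0 <- qr.Q(qr(matrix(rnorm(n_barcodes^2), n_barcodes)))
  fit <- ica::icafast(Xc, nc = n_barcodes, center = FALSE, maxit = maxit,
                      tol = tol, Rmat = R0, alg = "def", fun = "logcosh")
  if (!isTRUE(fit$converged))
    stop("ICA did not converge within ", maxit, " iterations")
  ## sources = Xc %*% t(Q) %*% R, so feature-space unmixing rows are
  ## t(R) %*% Q where Q is the whitening matrix; fit$M holds the mixing
  ## (feature-space response) directions of the same components
  W <- t(fit$R) %*% fit$Q
  W <- W / sqrt(rowSums(W^2))
  Sg <- t(fit$M) / sqrt(colSums(fit$M^2))
  ## sign conventions: each unmixing row has its largest-magnitude element
  ## positive; each signature is oriented so its dominant co-participation
  ## feature co-activates (positive), which makes the strength of a
  ## co-activation motif rise during its expression
  for (k in seq_len(nrow(W))) {
    m <- which.max(abs(W[k, ]))
    if (W[k, m] < 0) W[k, ] <- -W[k, ]
    m <- which.max(abs(Sg[k, ]))
    if (Sg[k, m] < 0) Sg[k, ] <- -Sg[k, ]
  }
  dimnames(W) <- list(paste0("barcode_", seq_len(nrow(W))),
                      F_std$feature_index$name)
  dimnames(Sg) <- dimnames(W)
  new("BarcodeModel", W = W, signatures = Sg,
      feature_index = F_std$feature_index,
      channels = F_std$channels, window_s = F_std$window_s, center = ctr,
      whitening = fit$Q, seed = as.integer(seed),
      converged = isTRUE(fit$converged))
}

#' Barcode strength time series
#'
#' The strength of each barcode over time is the dot product of its vector
#' with the co-participation vectors built from the raw (non-standardized)
#' amplitudes, one value per 250-ms window. By default the projection uses
#' the barcode's component signature (the ICA mixing direction): the
#' signature of a co-activation motif has non-negative alignment with the
#' motif's own raw-feature response, so its strength rises whenever the
#' motif is expressed. Projecting the unmixing row instead
#' (`use = "unmixing"`) isolates the component on standardized features but
#' is unstable on raw features, whose per-feature scales differ from the
#' standardized space the unmixing was learned in.
#'
#' @param model a [BarcodeModel-class].
#' @param F_raw a `"CoparticipationMatrix"` built with `use_std = FALSE` and
#'   the same feature index.
#' @param use `"signature"` (default) or `"unmixing"`.
#' @return An object of class `"StrengthSeries"`: list with `times_s`,
#'   `strength` (`n_windows x n_barcodes`), `window_s`, `use`.
#' @export
barcodeStrength <- function(model, F_raw, use = c("signature", "unmixing")) {
  use <- match.arg(use)
  stopifnot(is(model, "BarcodeModel"),
            inherits(F_raw, "CoparticipationMatrix"))
  if (!identical(model@feature_index$name, F_raw$feature_index$name))
    stop("feature index mismatch between model and co-participation matrix")
  V <- if (use == "signature") model@signatures else model@W
  S <- F_raw$F %*% t(V)
  colnames(S) <- rownames(model@W)
  structure(list(times_s = F_raw$times_s, strength = S,
                 window_s = F_raw$window_s, use = use),
            class = "StrengthSeries")
}

#' @export
print.StrengthSeries <- function(x, ...) {
  cat(sprintf("Barcode strengths: %d windows x %d barcodes (%g-s windows)\n",
              nrow(x$strength), ncol(x$strength), x$window_s))
  invisible(x)
}

## rank-based AUC (equivalent to the Mann-Whitney statistic)
.aucRank <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Barcode behavior-alignment score
#'
#' Scores how well each barcode's strength separates behavioral conditions:
#' the ROC area discriminating window-mean strength inside positive-condition
#' epochs from strength inside contrast epochs. 0.5 is uninformative, 1 means
#' strength is higher in every positive window. This package defines the
#' score as the ROC-AUC; windows are assigned to epochs by their centers.
#'
#' @param strengths a `"StrengthSeries"`.
#' @param events an [EventTable-class].
#' @param positive_condition condition counting as positive (e.g. `"novel"`).
#' @param contrast_condition condition to contrast against; default: all
#'   other epochs in the table.
#' @return Named numeric vector of scores in `[0, 1]`, one per barcode.
#' @export
barcodeScore <- function(strengths, events, positive_condition = "novel",
                         contrast_condition = NULL) {
  stopifnot(inherits(strengths, "StrengthSeries"), is(events, "EventTable"))
  ev <- events@events
  pos_ep <- ev[ev$condition == positive_condition, , drop = FALSE]
  neg_ep <- if (is.null(contrast_condition)) {
    ev[ev$condition != positive_condition, , drop = FALSE]
  } else ev[ev$condition == contrast_condition, , drop = FALSE]
  if (nrow(pos_ep) < 2 || nrow(neg_ep) < 2)
    stop("need at least 2 epochs per condition to score barcodes")
  t <- strengths$times_s
  in_epochs <- function(ep) {
    hit <- rep(FALSE, length(t))
    for (r in seq_len(nrow(ep)))
      hit <- hit | (t >= ep$start_s[r] & t < ep$end_s[r])
    hit
  }
  ipos <- in_epochs(pos_ep)
  ineg <- in_epochs(neg_ep)
  if (!any(ipos) || !any(ineg))
    stop("no strength windows fall inside the requested epochs")
  apply(strengths$strength, 2L, function(s) .aucRank(s[ipos], s[ineg]))
}

#' Run the full barcode pipeline on one recording
#'
#' Masked EMD per region, band assignment, amplitude matrix,
#' co-participation features (standardized and raw), ICA fit and strength
#' time series.
#'
#' @param rec a [Recording-class].
#' @param cfg a [PipelineConfig-class].
#' @param seed seed for the ICA initialization (default: `cfg@rng_seed`).
#' @param ... passed to [maskedEMD()].
#' @return List with `model` ([BarcodeModel-class]), `strengths`
#'   (`"StrengthSeries"`), `amplitude` (`"AmplitudeMatrix"`), `F_std` and
#'   `F_raw` (`"CoparticipationMatrix"`).
#' @export
barcodeAnalysis <- function(rec, cfg = pipelineConfig(),
                            seed = cfg@rng_seed, ...) {
  stopifnot(is(rec, "Recording"))
  selected <- lapply(setNames(rec@regions, rec@regions), function(reg)
    selectIMFs(maskedEMD(lfpSignal(rec, reg), rec@fs_hz, region = reg, ...),
               bands = cfg@bands))
  M <- amplitudeMatrix(selected)
  F_std <- coparticipation(M, cfg@coparticipation_window_s, use_std = TRUE)
  F_raw <- coparticipation(M, cfg@coparticipation_window_s, use_std = FALSE)
  model <- fitBarcodes(F_std, n_barcodes = cfg@n_barcodes, seed = seed)
  list(model = model, strengths = barcodeStrength(model, F_raw),
       amplitude = M, F_std = F_std, F_raw = F_raw)
}
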