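#' @include lfpbarcode-package.R
NULL

## central data containers are S4 with eager validity checking; analysis
## results are lightweight S3 records (see individual modules).

#' SpikeUnit: sorted spike times of one unit
#'
#' Holds the sorted spike times (seconds) of a single unit together with the
#' region label of the electrode it was recorded on. Spike sorting itself is
#' out of scope; times are taken as given (or simulated).
#'
#' @slot unit_id character scalar, unique within a recording.
#' @slot region region label (one of the recording's regions).
#' @slot spike_times_s strictly increasing, non-negative spike times in
#'   seconds, relative to the recording clock.
#' @exportClass SpikeUnit
setClass("SpikeUnit",
  slots = c(unit_id = "character", region = "character",
            spike_times_s = "numeric"))

setValidity("SpikeUnit", function(object) {
  msg <- character()
  if (length(object@unit_id) != 1L || !nzchar(object@unit_id))
    msg <- c(msg, "unit_id must be a non-empty string")
  if (length(object@region) != 1L)
    msg <- c(msg, "region must be a single label")
  st <- object@spike_times_s
  if (anyNA(st) || any(!is.finite(st)))
    msg <- c(msg, "spike times must be finite")
  else {
    if (length(st) && min(st) < 0)
      msg <- c(msg, "spike times must be non-negative")
    if (is.unsorted(st, strictly = TRUE))
      msg <- c(msg, "spike times must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeUnit
#'
#' @param unit_id unit identifier.
#' @param region region label.
#' @param spike_times_s strictly increasing non-negative spike times (s).
#' @return A [SpikeUnit-class] object.
#' @export
SpikeUnit <- function(unit_id, region, spike_times_s = numeric()) {
  new("SpikeUnit", unit_id = as.character(unit_id),
      region = as.character(region),
      spike_times_s = as.numeric(spike_times_s))
}

#' Recording: multi-region LFP plus sorted spike times
#'
#' The atom every analysis stage consumes: an LFP matrix with one row per
#' region (microvolts, common sampling rate) plus any number of spike-sorted
#' units, and subject/group metadata.
#'
#' @slot subject_id subject identifier.
#' @slot group `"control"` or `"lesion"`.
#' @slot regions ordered, unique region labels (default `c("OB","aPC","LEC")`).
#' @slot lfp numeric matrix `[n_regions x n_samples]`, microvolts.
#' @slot fs_hz sampling rate in Hz (LFPs are sampled at 1000 Hz by default).
#' @slot t0_s recording start time, seconds.
#' @slot units list of [SpikeUnit-class].
#' @exportClass Recording
setClass("Recording",
  slots = c(subject_id = "character", group = "character",
            regions = "character", lfp = "matrix", fs_hz = "numeric",
            t0_s = "numeric", units = "list"))

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@fs_hz) != 1L || !is.finite(object@fs_hz) ||
      object@fs_hz <= 0)
    msg <- c(msg, "fs_hz must be a single positive number")
  if (length(object@group) != 1L ||
      !object@group %in% c("control", "lesion"))
    msg <- c(msg, "group must be 'control' or 'lesion'")
  if (anyDuplicated(object@regions))
    msg <- c(msg, "region labels must be unique")
  if (!is.numeric(object@lfp))
    msg <- c(msg, "lfp must be a numeric matrix")
  else {
    if (nrow(object@lfp) != length(object@regions))
      msg <- c(msg, sprintf("lfp has %d rows but there are %d regions",
                            nrow(object@lfp), length(object@regions)))
    bad <- which(!is.finite(object@lfp))
    if (length(bad))
      msg <- c(msg, sprintf("lfp contains non-finite values (first at index %d)",
                            bad[1L]))
  }
  dur <- ncol(object@lfp) / object@fs_hz
  for (u in object@units) {
    if (!is(u, "SpikeUnit")) {
      msg <- c(msg, "units must be a list of SpikeUnit objects"); break
    }
    v <- validObject(u, test = TRUE)
    if (!isTRUE(v)) { msg <- c(msg, v); break }
    if (!u@region %in% object@regions)
      msg <- c(msg, sprintf("unit '%s' references unknown region '%s'",
                            u@unit_id, u@region))
    st <- u@spike_times_s
    if (length(st) &&
        (min(st) < object@t0_s || max(st) > object@t0_s + dur))
      msg <- c(msg, sprintf("unit '%s' has spikes outside the recording",
                            u@unit_id))
  }
  ids <- vapply(object@units, function(u) u@unit_id, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "unit ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param lfp numeric matrix `[n_regions x n_samples]`, microvolts.
#' @param fs_hz sampling rate, Hz.
#' @param regions ordered region labels (one per lfp row).
#' @param subject_id,group,t0_s metadata (see [Recording-class]).
#' @param units list of [SpikeUnit-class] objects.
#' @return A validated [Recording-class] object.
#' @export
Recording <- function(lfp, fs_hz = 1000, regions = c("OB", "aPC", "LEC"),
                      subject_id = "subject", group = "control", t0_s = 0,
                      units = list()) {
  if (is.vector(lfp)) lfp <- matrix(lfp, nrow = 1L)
  new("Recording", subject_id = as.character(subject_id),
      group = as.character(group), regions = as.character(regions),
      lfp = lfp, fs_hz = as.numeric(fs_hz), t0_s = as.numeric(t0_s),
      units = units)
}

#' EventTable: labeled behavioral epochs
#'
#' Rows of `epoch_id, label, start_s, end_s, condition` aligning neural
#' features to behavior (odor presentations, object-exploration bouts).
#' Epochs sharing a `label` must not overlap.
#'
#' @slot events data.frame with columns `epoch_id`, `label`, `start_s`,
#'   `end_s`, `condition` (one of `familiar`, `novel`, `habituation`,
#'   `other`).
#' @exportClass EventTable
setClass("EventTable", slots = c(events = "data.frame"))

.event_conditions <- c("familiar", "novel", "habituation", "other")
.event_columns <- c("epoch_id", "label", "start_s", "end_s", "condition")

setValidity("EventTable", function(object) {
  ev <- object@events
  msg <- character()
  if (!identical(names(ev), .event_columns))
    return(sprintf("events must have exactly the columns: %s",
                   paste(.event_columns, collapse = ", ")))
  if (nrow(ev)) {
    if (anyDuplicated(ev$epoch_id)) msg <- c(msg, "epoch_id must be unique")
    if (!all(ev$condition %in% .event_conditions))
      msg <- c(msg, sprintf("condition must be one of: %s",
                            paste(.event_conditions, collapse = ", ")))
    if (any(!is.finite(ev$start_s)) || any(!is.finite(ev$end_s)))
      msg <- c(msg, "start_s/end_s must be finite")
    else {
      bad <- which(ev$end_s <= ev$start_s)
      if (length(bad))
        msg <- c(msg, sprintf("end_s must exceed start_s (row %d, epoch '%s')",
                              bad[1L], ev$epoch_id[bad[1L]]))
      for (lab in unique(ev$label)) {
        sub <- ev[ev$label == lab, , drop = FALSE]
        if (nrow(sub) < 2L) next
        o <- order(sub$start_s)
        sub <- sub[o, , drop = FALSE]
        ov <- which(sub$start_s[-1L] < sub$end_s[-nrow(sub)])
        if (length(ov))
          msg <- c(msg, sprintf(
            "epochs '%s' and '%s' overlap within label stream '%s'",
            sub$epoch_id[ov[1L]], sub$epoch_id[ov[1L] + 1L], lab))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EventTable
#'
#' @param events data.frame with columns `epoch_id`, `label`, `start_s`,
#'   `end_s`, `condition`.
#' @return A validated [EventTable-class] object.
#' @export
EventTable <- function(events) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  events <- events[, .event_columns]
  events$epoch_id <- as.character(events$epoch_id)
  events$label <- as.character(events$label)
  events$start_s <- as.numeric(events$start_s)
  events$end_s <- as.numeric(events$end_s)
  events$condition <- as.character(events$condition)
  rownames(events) <- NULL
  new("EventTable", events = events)
}

#' PipelineConfig: shared analysis parameters
#'
#' Holds the frequency-band table and the tuning parameters every stage
#' shares. Defaults mirror the analysis conditions of the study design:
#' 2-s Welch segments with 50% overlap, 250-ms co-participation windows,
#' 8 barcodes, 18 phase bins for the modulation index, 80/20 animal-wise
#' decoding splits with 500 cross-validation iterations and 100 label
#' shuffles for the chance interval.
#'
#' @slot bands band definition table (see [defaultBands()]).
#' @slot psd_segment_s Welch segment length, seconds.
#' @slot psd_overlap Welch segment overlap fraction.
#' @slot coparticipation_window_s co-participation window, seconds.
#' @slot n_barcodes number of ICA components ("barcodes").
#' @slot pac_phase_band,pac_amp_band band names for phase-amplitude coupling.
#' @slot pac_n_bins phase bins for the modulation index.
#' @slot decode_train_frac fraction of subjects in each training split.
#' @slot decode_n_iter cross-validation iterations.
#' @slot null_n_shuffles label shuffles for the chance interval.
#' @slot rng_seed integer seed.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  slots = c(bands = "data.frame", psd_segment_s = "numeric",
            psd_overlap = "numeric", coparticipation_window_s = "numeric",
            n_barcodes = "integer", pac_phase_band = "character",
            pac_amp_band = "character", pac_n_bins = "integer",
            decode_train_frac = "numeric", decode_n_iter = "integer",
            null_n_shuffles = "integer", rng_seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  v <- .validateBands(object@bands)
  if (!isTRUE(v)) msg <- c(msg, v)
  if (object@psd_segment_s <= 0) msg <- c(msg, "psd_segment_s must be > 0")
  if (object@psd_overlap < 0 || object@psd_overlap >= 1)
    msg <- c(msg, "psd_overlap must be in [0, 1)")
  if (object@coparticipation_window_s <= 0)
    msg <- c(msg, "coparticipation_window_s must be > 0")
  if (object@n_barcodes < 1L) msg <- c(msg, "n_barcodes must be >= 1")
  if (object@pac_n_bins < 4L) msg <- c(msg, "pac_n_bins must be >= 4")
  if (object@decode_train_frac <= 0 || object@decode_train_frac >= 1)
    msg <- c(msg, "decode_train_frac must be in (0, 1)")
  if (object@decode_n_iter < 1L) msg <- c(msg, "decode_n_iter must be >= 1")
  if (object@null_n_shuffles < 2L)
    msg <- c(msg, "null_n_shuffles must be >= 2")
  if (!all(c(object@pac_phase_band, object@pac_amp_band) %in%
           object@bands$name))
    msg <- c(msg, "pac_phase_band/pac_amp_band must name defined bands")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param bands band definition table, default [defaultBands()].
#' @param psd_segment_s,psd_overlap Welch parameters (2 s, 50%).
#' @param coparticipation_window_s co-participation window (0.25 s).
#' @param n_barcodes number of barcodes (8).
#' @param pac_phase_band,pac_amp_band bands for PAC ("theta", "gamma").
#' @param pac_n_bins phase bins for the modulation index (18).
#' @param decode_train_frac,decode_n_iter,null_n_shuffles decoding
#'   parameters (0.8, 500, 100).
#' @param rng_seed integer seed.
#' @return A validated [PipelineConfig-class] object.
#' @export
pipelineConfig <- function(bands = defaultBands(), psd_segment_s = 2,
                           psd_overlap = 0.5,
                           coparticipation_window_s = 0.25, n_barcodes = 8,
                           pac_phase_band = "theta", pac_amp_band = "gamma",
                           pac_n_bins = 18, decode_train_frac = 0.8,
                           decode_n_iter = 500, null_n_shuffles = 100,
                           rng_seed = 1) {
  new("PipelineConfig", bands = bands,
      psd_segment_s = as.numeric(psd_segment_s),
      psd_overlap = as.numeric(psd_overlap),
      coparticipation_window_s = as.numeric(coparticipation_window_s),
      n_barcodes = as.integer(n_barcodes),
      pac_phase_band = pac_phase_band, pac_amp_band = pac_amp_band,
      pac_n_bins = as.integer(pac_n_bins),
      decode_train_frac = as.numeric(decode_train_frac),
      decode_n_iter = as.integer(decode_n_iter),
      null_n_shuffles = as.integer(null_n_shuffles),
      rng_seed = as.integer(rng_seed))
}

#' BarcodeModel: ICA weight vectors over co-participation features
#'
#' The fitted barcode model: unit-norm weight vectors (one per barcode) over
#' the upper-triangle co-participation features, the feature index mapping
#' matrix cells to feature positions, and the whitening metadata needed to
#' reproduce the fit.
#'
#' @slot W weight matrix `[n_barcodes x n_features]`, unit-norm rows, sign
#'   fixed so each row's largest-magnitude element is positive.
#' @slot signatures component signatures `[n_barcodes x n_features]`: the
#'   unit-norm ICA mixing directions mapped to feature space. A barcode's
#'   weight vector is its detector (it extracts the component from data);
#'   its signature is the co-participation pattern the component imprints
#'   on the features, and is the object to render as the barcode grid or to
#'   compare against planted ground truth.
#' @slot feature_index data.frame with columns `i`, `j`, `name` covering the
#'   upper triangle (including the diagonal) exactly once.
#' @slot channels ordered `(region, band)` channel labels.
#' @slot window_s co-participation window length, seconds.
#' @slot center per-feature means removed before ICA.
#' @slot whitening PCA whitening matrix used before the fixed-point ICA.
#' @slot seed integer seed used for the ICA initialization.
#' @slot converged logical convergence flag.
#' @exportClass BarcodeModel
setClass("BarcodeModel",
  slots = c(W = "matrix", signatures = "matrix",
            feature_index = "data.frame", channels = "character",
            window_s = "numeric", center = "numeric",
            whitening = "matrix", seed = "integer",
            converged = "logical"))

setValidity("BarcodeModel", function(object) {
  msg <- character()
  if (!identical(names(object@feature_index), c("i", "j", "name")))
    msg <- c(msg, "feature_index must have columns i, j, name")
  if (nrow(object@feature_index) != ncol(object@W))
    msg <- c(msg, "feature_index rows must match W columns")
  n <- length(object@channels)
  if (nrow(object@feature_index) != n * (n + 1) / 2)
    msg <- c(msg, "feature_index must cover the upper triangle exactly once")
  nrm <- sqrt(rowSums(object@W^2))
  if (any(abs(nrm - 1) > 1e-8))
    msg <- c(msg, "rows of W must be unit-norm")
  if (!identical(dim(object@signatures), dim(object@W)))
    msg <- c(msg, "signatures must have the same shape as W")
  if (length(msg)) msg else TRUE
})
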