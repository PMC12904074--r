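#' @include AllClasses.R
NULL

#' Accessors for Recording, SpikeUnit and EventTable objects
#'
#' Slot access for the central containers: sampling rate, duration, number of
#' samples, region labels, the LFP matrix or a single region's signal, the
#' spike units, and subject metadata.
#'
#' @param x a [Recording-class], [SpikeUnit-class] or [EventTable-class].
#' @param region region label for `lfpSignal`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname accessors
#' @export
setGeneric("lfpMatrix", function(x) standardGeneric("lfpMatrix"))
#' @rdname accessors
#' @export
setGeneric("lfpSignal", function(x, region) standardGeneric("lfpSignal"))
#' @rdname accessors
#' @export
setGeneric("spikeUnits", function(x) standardGeneric("spikeUnits"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))
#' @rdname accessors
#' @export
setGeneric("unitRegion", function(x) standardGeneric("unitRegion"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("eventData", function(x) standardGeneric("eventData"))
#' @rdname accessors
#' @export
setGeneric("meanRate", function(x) standardGeneric("meanRate"))

#' @rdname accessors
setMethod("samplingRate", "Recording", function(x) x@fs_hz)
#' @rdname accessors
setMethod("nSamples", "Recording", function(x) ncol(x@lfp))
#' @rdname accessors
setMethod("duration", "Recording", function(x) ncol(x@lfp) / x@fs_hz)
#' @rdname accessors
setMethod("regionNames", "Recording", function(x) x@regions)
#' @rdname accessors
setMethod("lfpMatrix", "Recording", function(x) x@lfp)
#' @rdname accessors
setMethod("lfpSignal", "Recording", function(x, region) {
  i <- match(region, x@regions)
  if (is.na(i)) stop("unknown region '", region, "'")
  x@lfp[i, ]
})
#' @rdname accessors
setMethod("spikeUnits", "Recording", function(x) x@units)
#' @rdname accessors
setMethod("subjectId", "Recording", function(x) x@subject_id)
#' @rdname accessors
setMethod("groupLabel", "Recording", function(x) x@group)
#' @rdname accessors
setMethod("meanRate", "Recording", function(x) {
  dur <- duration(x)
  vapply(x@units, function(u) length(u@spike_times_s) / dur, numeric(1)) |>
    setNames(vapply(x@units, function(u) u@unit_id, character(1)))
})

#' @rdname accessors
setMethod("unitId", "SpikeUnit", function(x) x@unit_id)
#' @rdname accessors
setMethod("unitRegion", "SpikeUnit", function(x) x@region)
#' @rdname accessors
setMethod("spikeTimes", "SpikeUnit", function(x) x@spike_times_s)

#' @rdname accessors
setMethod("eventData", "EventTable", function(x) x@events)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s' (%s): %d region(s) x %d samples @ %g Hz (%.1f s), %d unit(s)\n",
              object@subject_id, object@group, nrow(object@lfp),
              ncol(object@lfp), object@fs_hz, duration(object),
              length(object@units)))
  cat("  regions:", paste(object@regions, collapse = ", "), "\n")
})

setMethod("show", "SpikeUnit", function(object) {
  cat(sprintf("SpikeUnit '%s' (%s): %d spikes\n", object@unit_id,
              object@region, length(object@spike_times_s)))
})

setMethod("show", "EventTable", function(object) {
  ev <- object@events
  cat(sprintf("EventTable: %d epoch(s)", nrow(ev)))
  if (nrow(ev)) {
    tab <- table(ev$condition)
    cat(" [", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "]", sep = "")
  }
  cat("\n")
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat("  bands:", paste(sprintf("%s %g-%g Hz", object@bands$name,
                                object@bands$lo_hz, object@bands$hi_hz),
                        collapse = "; "), "\n")
  cat(sprintf("  Welch: %g-s segments, %g overlap | window: %g s | barcodes: %d\n",
              object@psd_segment_s, object@psd_overlap,
              object@coparticipation_window_s, object@n_barcodes))
  cat(sprintf("  PAC: %s phase x %s amplitude, %d bins\n",
              object@pac_phase_band, object@pac_amp_band, object@pac_n_bins))
  cat(sprintf("  decode: train %g, %d iterations, %d shuffles, seed %d\n",
              object@decode_train_frac, object@decode_n_iter,
              object@null_n_shuffles, object@rng_seed))
})

setMethod("show", "BarcodeModel", function(object) {
  cat(sprintf("BarcodeModel: %d barcode(s) over %d co-participation features (%d channels, %.3g-s windows)\n",
              nrow(object@W), ncol(object@W), length(object@channels),
              object@window_s))
  cat("  channels:", paste(object@channels, collapse = ", "), "\n")
  cat("  converged:", object@converged, "\n")
})

#' Barcode model accessors
#'
#' @param x a [BarcodeModel-class].
#' @name barcode-accessors
NULL

#' @rdname barcode-accessors
#' @export
setGeneric("barcodeWeights", function(x) standardGeneric("barcodeWeights"))
#' @rdname barcode-accessors
#' @export
setGeneric("featureIndex", function(x) standardGeneric("featureIndex"))
#' @rdname barcode-accessors
#' @export
setGeneric("barcodeSignatures",
           function(x) standardGeneric("barcodeSignatures"))
#' @rdname barcode-accessors
setMethod("barcodeWeights", "BarcodeModel", function(x) x@W)
#' @rdname barcode-accessors
setMethod("featureIndex", "BarcodeModel", function(x) x@feature_index)
#' @rdname barcode-accessors
setMethod("barcodeSignatures", "BarcodeModel", function(x) x@signatures)
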