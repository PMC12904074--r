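#' Read and write Recording objects (HDF5)
#'
#' Recordings are stored in a documented HDF5 layout: dataset `/lfp`
#' (float64, `n_regions x n_samples`), root attributes `fs_hz`, `t0_s`,
#' `subject_id`, `group`, string dataset `/regions`, and one group
#' `/units/<unit_id>` per unit holding `spike_times_s` (float64) with a
#' `region` attribute. `readRecording(writeRecording(x))` round-trips the
#' LFP payload bitwise and all metadata exactly. Validation is eager: schema
#' violations and non-finite samples raise immediately with file context.
#'
#' @param path HDF5 file path.
#' @param rec a [Recording-class].
#' @return `readRecording` returns a validated [Recording-class];
#'   `writeRecording` invisibly returns `path`.
#' @seealso [readEvents()], [sliceEpoch()]
#' @export
readRecording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  contents <- rhdf5::h5ls(path)
  have <- file.path(ifelse(contents$group == "/", "", contents$group),
                    contents$name)
  have <- sub("^/*", "/", have)
  for (ds in c("/lfp", "/regions"))
    if (!ds %in% have)
      stop("schema error in '", path, "': missing dataset ", ds)
  att <- rhdf5::h5readAttributes(path, "/")
  for (a in c("fs_hz", "t0_s", "subject_id", "group"))
    if (is.null(att[[a]]))
      stop("schema error in '", path, "': missing attribute ", a)
  lfp <- rhdf5::h5read(path, "lfp")
  if (is.null(dim(lfp))) lfp <- matrix(lfp, nrow = 1L)
  bad <- which(!is.finite(lfp))
  if (length(bad))
    stop("data error in '", path, "': non-finite lfp value at index ",
         bad[1L])
  regions <- as.character(rhdf5::h5read(path, "regions"))
  units <- list()
  unit_groups <- contents$name[contents$group == "/units" &
                               contents$otype == "H5I_GROUP"]
  for (uid in sort(unit_groups)) {
    upath <- paste0("units/", uid)
    st <- as.numeric(rhdf5::h5read(path, paste0(upath, "/spike_times_s")))
    uatt <- rhdf5::h5readAttributes(path, upath)
    if (is.null(uatt$region))
      stop("schema error in '", path, "': unit '", uid,
           "' is missing its region attribute")
    units[[length(units) + 1L]] <- SpikeUnit(uid, uatt$region, st)
  }
  Recording(lfp = lfp, fs_hz = as.numeric(att$fs_hz), regions = regions,
            subject_id = as.character(att$subject_id),
            group = as.character(att$group), t0_s = as.numeric(att$t0_s),
            units = units)
}

#' @rdname readRecording
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  validObject(rec)
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop("cannot create file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(rec@lfp, path, "lfp")
  rhdf5::h5write(rec@regions, path, "regions")
  if (length(rec@units)) {
    rhdf5::h5createGroup(path, "units")
    for (u in rec@units) {
      g <- paste0("units/", u@unit_id)
      rhdf5::h5createGroup(path, g)
      rhdf5::h5write(u@spike_times_s, path, paste0(g, "/spike_times_s"))
    }
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(rec@fs_hz, fid, "fs_hz")
  rhdf5::h5writeAttribute(rec@t0_s, fid, "t0_s")
  rhdf5::h5writeAttribute(rec@subject_id, fid, "subject_id")
  rhdf5::h5writeAttribute(rec@group, fid, "group")
  for (u in rec@units) {
    gid <- rhdf5::H5Gopen(fid, paste0("units/", u@unit_id))
    rhdf5::h5writeAttribute(u@region, gid, "region")
    rhdf5::H5Gclose(gid)
  }
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read and write event tables (CSV)
#'
#' Events live in plain CSV with the exact header
#' `epoch_id,label,start_s,end_s,condition` so behavioral re-labeling never
#' touches signal files. Epoch invariants (positive duration, no overlap
#' within a label stream, known condition labels) are validated on read and
#' write.
#'
#' @param path CSV file path.
#' @param events an [EventTable-class].
#' @return `readEvents` returns a validated [EventTable-class];
#'   `writeEvents` invisibly returns `path`.
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(epoch_id = "character", label = "character",
                                start_s = "numeric", end_s = "numeric",
                                condition = "character"))
  if (!identical(names(df), .event_columns))
    stop("schema error in '", path, "': expected header ",
         paste(.event_columns, collapse = ","))
  EventTable(df)
}

#' @rdname readEvents
#' @export
writeEvents <- function(events, path) {
  stopifnot(is(events, "EventTable"))
  validObject(events)
  write.csv(events@events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write pipeline configurations (JSON)
#'
#' JSON mirrors the [PipelineConfig-class] field names; the band table is
#' stored as a list of `{name, lo_hz, hi_hz}` records.
#'
#' @param path JSON file path.
#' @param cfg a [PipelineConfig-class].
#' @return `readConfig` returns a validated [PipelineConfig-class];
#'   `writeConfig` invisibly returns `path`.
#' @export
readConfig <- function(path) {
  x <- jsonlite::fromJSON(path)
  args <- x[intersect(names(x), c(
    "psd_segment_s", "psd_overlap", "coparticipation_window_s",
    "n_barcodes", "pac_phase_band", "pac_amp_band", "pac_n_bins",
    "decode_train_frac", "decode_n_iter", "null_n_shuffles", "rng_seed"))]
  if (!is.null(x$bands)) args$bands <- as.data.frame(x$bands)
  do.call(pipelineConfig, args)
}

#' @rdname readConfig
#' @export
writeConfig <- function(cfg, path) {
  stopifnot(is(cfg, "PipelineConfig"))
  x <- list(bands = cfg@bands, psd_segment_s = cfg@psd_segment_s,
            psd_overlap = cfg@psd_overlap,
            coparticipation_window_s = cfg@coparticipation_window_s,
            n_barcodes = cfg@n_barcodes,
            pac_phase_band = cfg@pac_phase_band,
            pac_amp_band = cfg@pac_amp_band, pac_n_bins = cfg@pac_n_bins,
            decode_train_frac = cfg@decode_train_frac,
            decode_n_iter = cfg@decode_n_iter,
            null_n_shuffles = cfg@null_n_shuffles, rng_seed = cfg@rng_seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Cut one epoch out of a Recording
#'
#' Time runs in seconds; sample indices are `floor(t * fs)` on half-open
#' intervals `[start_s, end_s)`, so adjacent slices tile the recording with
#' no duplicated or lost samples. Spike times are filtered to the same
#' half-open interval (a spike at exactly `end_s` is excluded) and
#' re-referenced so the epoch starts at 0.
#'
#' @param rec a [Recording-class].
#' @param start_s,end_s epoch bounds in seconds, within the recording.
#' @return A [Recording-class] covering only the epoch.
#' @export
sliceEpoch <- function(rec, start_s, end_s) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs_hz
  dur <- duration(rec)
  if (end_s <= start_s)
    stop("end_s must exceed start_s")
  if (start_s < rec@t0_s - 1e-12 || end_s > rec@t0_s + dur + 1e-12)
    stop(sprintf("epoch [%g, %g) is outside the recording [%g, %g)",
                 start_s, end_s, rec@t0_s, rec@t0_s + dur))
  i0 <- floor((start_s - rec@t0_s) * fs)   # 0-based first sample
  i1 <- floor((end_s - rec@t0_s) * fs)     # 0-based one-past-last
  if (i1 <= i0) stop("epoch contains no samples")
  lfp <- rec@lfp[, (i0 + 1L):i1, drop = FALSE]
  ## spikes in the half-open epoch, capped at the sliced sample extent
  dur_slice <- (i1 - i0) / fs
  units <- lapply(rec@units, function(u) {
    st <- u@spike_times_s
    keep <- st >= start_s & st < end_s & st - start_s < dur_slice
    SpikeUnit(u@unit_id, u@region, st[keep] - start_s)
  })
  Recording(lfp = lfp, fs_hz = fs, regions = rec@regions,
            subject_id = rec@subject_id, group = rec@group, t0_s = 0,
            units = units)
}
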