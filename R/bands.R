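#' Frequency band definitions
#'
#' The analysis works on the theta (3-12 Hz), beta (15-35 Hz) and gamma
#' (36-95 Hz) bands of the olfactory network. Bands are plain data.frames
#' with columns `name`, `lo_hz`, `hi_hz` so users can add or replace bands.
#'
#' @return `defaultBands()` returns the three default bands; `bandDef()`
#'   builds a one-row band table.
#' @examples
#' defaultBands()
#' bandDef("slow_gamma", 36, 60)
#' @export
defaultBands <- function() {
  data.frame(name = c("theta", "beta", "gamma"),
             lo_hz = c(3, 15, 36), hi_hz = c(12, 35, 95),
             stringsAsFactors = FALSE)
}

#' @rdname defaultBands
#' @param name band name.
#' @param lo_hz,hi_hz band edges in Hz, `0 < lo_hz < hi_hz`.
#' @export
bandDef <- function(name, lo_hz, hi_hz) {
  b <- data.frame(name = as.character(name), lo_hz = as.numeric(lo_hz),
                  hi_hz = as.numeric(hi_hz), stringsAsFactors = FALSE)
  v <- .validateBands(b)
  if (!isTRUE(v)) stop(v)
  b
}

## band table sanity; fs_hz bounds checked where a signal is at hand
.validateBands <- function(bands, fs_hz = NULL) {
  if (!is.data.frame(bands) ||
      !all(c("name", "lo_hz", "hi_hz") %in% names(bands)))
    return("bands must be a data.frame with columns name, lo_hz, hi_hz")
  if (anyDuplicated(bands$name)) return("band names must be unique")
  if (any(bands$lo_hz <= 0) || any(bands$hi_hz <= bands$lo_hz))
    return("each band needs 0 < lo_hz < hi_hz")
  if (!is.null(fs_hz) && any(bands$hi_hz >= fs_hz / 2))
    return(sprintf("band edges must stay below the Nyquist frequency %g Hz",
                   fs_hz / 2))
  TRUE
}

.getBand <- function(bands, name) {
  i <- match(name, bands$name)
  if (is.na(i)) stop("band '", name, "' is not defined")
  bands[i, , drop = FALSE]
}
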