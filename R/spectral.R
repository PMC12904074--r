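#' Welch power spectral density
#'
#' Mean of Hann-windowed, overlapping periodograms (one-sided, density
#' scaling, microvolts squared per Hz). Defaults (2-s segments, 50% overlap)
#' resolve the 3 Hz theta edge with at least 0.5 Hz resolution. No detrending
#' or notch filtering is applied; an optional 50 Hz notch is available in
#' [bandpassAnalytic()] workflows if line noise is a concern, since 50 Hz
#' falls inside the gamma band.
#'
#' @param x numeric signal (one region), microvolts.
#' @param fs_hz sampling rate, Hz.
#' @param segment_s segment length in seconds (default 2).
#' @param overlap overlap fraction (default 0.5).
#' @return An object of class `"PSDResult"`: list with `freqs_hz`, `psd`
#'   (power per Hz), `segment_s`, `overlap`, `n_segments`.
#' @examples
#' fs <- 1000
#' x <- cos(2 * pi * 8 * seq(0, 10, by = 1 / fs)[-1])
#' p <- welchPSD(x, fs)
#' p$freqs_hz[which.max(p$psd)]  # 8 Hz
#' @export
welchPSD <- function(x, fs_hz, segment_s = 2, overlap = 0.5) {
  sp <- .welchSpectra(x, NULL, fs_hz, segment_s, overlap)
  structure(list(freqs_hz = sp$freqs_hz, psd = sp$Sxx,
                 segment_s = sp$segment_s, overlap = sp$overlap,
                 n_segments = sp$n_segments),
            class = "PSDResult")
}

#' @export
print.PSDResult <- function(x, ...) {
  cat(sprintf("Welch PSD: %d bins up to %g Hz (%g-s segments x %d, overlap %g)\n",
              length(x$freqs_hz), max(x$freqs_hz), x$segment_s,
              x$n_segments, x$overlap))
  invisible(x)
}

#' Band power in dB
#'
#' Integrates the Welch PSD over the frequency bins whose centers fall in the
#' closed band `[lo_hz, hi_hz]` (trapezoid rule) and converts to decibels.
#' The dB reference is 1 microvolt squared of band-integrated power; absolute
#' levels therefore depend on the recording gain and only differences between
#' conditions are scientifically meaningful. An identically zero signal
#' yields `-Inf` with `zero_signal = TRUE`.
#'
#' @param x numeric signal, microvolts.
#' @param fs_hz sampling rate, Hz.
#' @param band one-row band table (see [bandDef()]) or band name resolved in
#'   `bands`.
#' @param segment_s,overlap Welch parameters.
#' @param bands band table used when `band` is given by name.
#' @return An object of class `"BandPower"`: list with `band`, `power_db`,
#'   `power_uv2`, `zero_signal`.
#' @examples
#' fs <- 1000
#' x <- cos(2 * pi * 8 * seq(0, 10, by = 1 / fs)[-1])
#' bandPowerDb(x, fs, "theta")$power_db  # ~ 10*log10(0.5)
#' @export
bandPowerDb <- function(x, fs_hz, band, segment_s = 2, overlap = 0.5,
                        bands = defaultBands()) {
  if (is.character(band)) band <- .getBand(bands, band)
  v <- .validateBands(band, fs_hz)
  if (!isTRUE(v)) stop(v)
  p <- welchPSD(x, fs_hz, segment_s, overlap)
  pw <- .bandIntegral(p$freqs_hz, p$psd, band$lo_hz, band$hi_hz)
  structure(list(band = band,
                 power_db = if (pw > 0) 10 * log10(pw) else -Inf,
                 power_uv2 = pw, zero_signal = pw == 0),
            class = "BandPower")
}

#' @export
print.BandPower <- function(x, ...) {
  cat(sprintf("%s (%g-%g Hz): %.2f dB re 1 uV^2\n", x$band$name,
              x$band$lo_hz, x$band$hi_hz, x$power_db))
  invisible(x)
}

#' Band-averaged cross-spectral coherence
#'
#' Welch cross-spectrum between two simultaneously recorded signals;
#' magnitude-squared coherence `msc = |Sxy|^2 / (Sxx * Syy)` per frequency
#' bin, summarized per band as the mean of `sqrt(msc)` over in-band bins.
#' The square-root (coherence magnitude) summary is used because printed
#' coherence values in this literature (0.27-0.62) correspond to magnitude,
#' not squared coherence; set `summary = "msc"` for the squared version.
#' Fewer than 8 segments gives a strongly biased estimate: the result is
#' flagged `high_bias` and a warning is emitted.
#'
#' @param x,y equal-length signals from two regions.
#' @param fs_hz sampling rate, Hz.
#' @param bands band table (default [defaultBands()]).
#' @param segment_s,overlap Welch parameters.
#' @param summary `"magnitude"` (default) or `"msc"`.
#' @return An object of class `"CoherenceResult"`: list with `freqs_hz`,
#'   `msc`, `band_means` (named per band), `n_segments`, `high_bias`.
#' @export
bandCoherence <- function(x, y, fs_hz, bands = defaultBands(),
                          segment_s = 2, overlap = 0.5,
                          summary = c("magnitude", "msc")) {
  summary <- match.arg(summary)
  if (length(x) != length(y)) stop("x and y must have equal length")
  v <- .validateBands(bands, fs_hz)
  if (!isTRUE(v)) stop(v)
  sp <- .welchSpectra(x, y, fs_hz, segment_s, overlap)
  high_bias <- sp$n_segments < 8
  if (high_bias)
    warning(sprintf(
      "only %d Welch segments: coherence estimates are strongly biased upward",
      sp$n_segments))
  msc <- Mod(sp$Sxy)^2 / (sp$Sxx * sp$Syy)
  msc[!is.finite(msc)] <- 0       # zero-power bins carry no coherence
  msc <- pmin(pmax(msc, 0), 1)
  band_means <- vapply(seq_len(nrow(bands)), function(i) {
    idx <- which(sp$freqs_hz >= bands$lo_hz[i] &
                 sp$freqs_hz <= bands$hi_hz[i])
    if (!length(idx)) return(NA_real_)
    if (summary == "magnitude") mean(sqrt(msc[idx])) else mean(msc[idx])
  }, numeric(1))
  names(band_means) <- bands$name
  structure(list(freqs_hz = sp$freqs_hz, msc = msc,
                 band_means = band_means, n_segments = sp$n_segments,
                 summary = summary, high_bias = high_bias),
            class = "CoherenceResult")
}

#' @export
print.CoherenceResult <- function(x, ...) {
  cat(sprintf("Coherence (%d segments%s): %s\n", x$n_segments,
              if (x$high_bias) ", HIGH BIAS" else "",
              paste(sprintf("%s %.3f", names(x$band_means), x$band_means),
                    collapse = ", ")))
  invisible(x)
}

#' Normalized time-lagged cross-correlation and its absolute maximum
#'
#' Coefficient-normalized cross-correlation (means removed; autocorrelation
#' at lag 0 equals 1) scanned over lags in `[-max_lag_s, +max_lag_s]`. The
#' absolute maximum of the curve is the coupling-strength index; its sign is
#' ignored, so an inverted copy of a signal scores the same as the signal.
#' Exact ties are broken toward lag 0, then toward the negative lag.
#'
#' @param x,y equal-length signals.
#' @param fs_hz sampling rate, Hz.
#' @param max_lag_s maximum lag to scan, seconds (must be < duration / 2).
#' @return An object of class `"XCorrResult"`: list with `lags_s`, `r`,
#'   `peak_abs`, `peak_lag_s`.
#' @examples
#' fs <- 100; x <- rnorm(1000)
#' y <- c(rep(0, 10), x[1:990])   # x delayed by 10 samples
#' maxXCorr(x, y, fs, 0.5)$peak_lag_s  # 0.1 s
#' @export
maxXCorr <- function(x, y, fs_hz, max_lag_s) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (max_lag_s >= n / fs_hz / 2)
    stop("max_lag_s must be below half the signal duration")
  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  if (denom == 0)
    stop("correlation undefined: at least one signal is constant")
  maxlag <- floor(max_lag_s * fs_hz)
  ## full linear cross-correlation via FFT: r[k] = sum_t x[t] y[t+k]
  nfft <- stats::nextn(2 * n - 1, 2)
  X <- fft(c(xc, numeric(nfft - n)))
  Y <- fft(c(yc, numeric(nfft - n)))
  cc <- Re(fft(Conj(X) * Y, inverse = TRUE)) / nfft
  lags <- (-maxlag):maxlag
  r <- numeric(length(lags))
  r[lags >= 0] <- cc[lags[lags >= 0] + 1L]
  r[lags < 0] <- cc[nfft + lags[lags < 0] + 1L]
  r <- r / denom
  if (any(abs(r) > 1 + 1e-9))
    stop("internal error: |r| exceeded 1")
  ## tie-break: order candidates by |lag| then negative before positive
  ord <- order(abs(lags), lags)
  best <- ord[which.max(abs(r)[ord])]
  structure(list(lags_s = lags / fs_hz, r = r, peak_abs = abs(r[best]),
                 peak_lag_s = lags[best] / fs_hz),
            class = "XCorrResult")
}

#' @export
print.XCorrResult <- function(x, ...) {
  cat(sprintf("Max |xcorr| = %.3f at lag %+.4g s (scanned +/- %g s)\n",
              x$peak_abs, x$peak_lag_s, max(x$lags_s)))
  invisible(x)
}
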