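## Internal signal helpers shared by the spectral, coupling and EMD modules.

## analytic signal via the frequency-domain Hilbert transform
.analytic <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

## phase unwrapping (adds multiples of 2*pi so jumps stay below pi)
.unwrap <- function(p) {
  dp <- diff(p)
  jumps <- -round(dp / (2 * pi)) * 2 * pi
  p + c(0, cumsum(jumps))
}

.wrapPhase <- function(p) {
  ((p + pi) %% (2 * pi)) - pi
}

## Hann window
.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

## segment starts for Welch averaging
.welchStarts <- function(n, nper, overlap) {
  step <- max(1L, floor(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  starts
}

## one-sided Welch auto/cross spectra of one or two equal-length signals.
## Returns density-scaled spectra (power per Hz); Sxy is complex.
.welchSpectra <- function(x, y = NULL, fs, segment_s, overlap) {
  n <- length(x)
  nper <- round(segment_s * fs)
  if (nper < 2) stop("segment too short: fewer than 2 samples per segment")
  if (n < 2 * nper)
    stop(sprintf(
      "signal too short for Welch averaging: need at least %d samples (2 segments of %g s), got %d",
      2 * nper, segment_s, n))
  w <- .hann(nper)
  U <- sum(w^2)
  starts <- .welchStarts(n, nper, overlap)
  nf <- floor(nper / 2) + 1L
  Sxx <- numeric(nf)
  Syy <- if (!is.null(y)) numeric(nf) else NULL
  Sxy <- if (!is.null(y)) complex(nf) else NULL
  for (s in starts) {
    idx <- s:(s + nper - 1L)
    X <- fft(w * x[idx])[1:nf]
    Sxx <- Sxx + Re(X * Conj(X))
    if (!is.null(y)) {
      Y <- fft(w * y[idx])[1:nf]
      Syy <- Syy + Re(Y * Conj(Y))
      Sxy <- Sxy + X * Conj(Y)
    }
  }
  k <- length(starts)
  scale <- 1 / (fs * U * k)
  one_sided <- rep(2, nf)
  one_sided[1L] <- 1
  if (nper %% 2 == 0) one_sided[nf] <- 1
  freqs <- (0:(nf - 1)) * fs / nper
  out <- list(freqs_hz = freqs, Sxx = Sxx * scale * one_sided,
              n_segments = k, segment_s = nper / fs, overlap = overlap)
  if (!is.null(y)) {
    out$Syy <- Syy * scale * one_sided
    out$Sxy <- Sxy * scale * one_sided
  }
  out
}

## trapezoidal integral over frequency bins whose centers fall inside the
## closed band [lo, hi] (deterministic across platforms)
.bandIntegral <- function(freqs, psd, lo, hi) {
  idx <- which(freqs >= lo & freqs <= hi)
  if (length(idx) == 0)
    stop(sprintf(
      "no frequency bins inside [%g, %g] Hz; increase segment_s for finer resolution",
      lo, hi))
  if (length(idx) == 1) return(psd[idx] * (freqs[2] - freqs[1]))
  f <- freqs[idx]
  p <- psd[idx]
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

## 1/f^alpha Gaussian noise, unit variance, via spectral shaping of white
## noise; spectrum flattened below lo_cut_hz to keep the process stationary
.oneOverFNoise <- function(n, fs, alpha, lo_cut_hz = 1) {
  white <- rnorm(n)
  X <- fft(white)
  freqs <- c(0, seq_len(n - 1)) * fs / n
  freqs <- pmin(freqs, fs - freqs)         # two-sided frequency axis
  g <- pmax(freqs, lo_cut_hz)^(-alpha / 2)
  g[1L] <- 0                               # remove DC
  x <- Re(fft(X * g, inverse = TRUE) / n)
  x / sd(x)
}

## deterministic per-purpose substream seeds below 2^31
.subSeed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2017L + 7919L * as.integer(k) %% 1000003L
}
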