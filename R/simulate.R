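#' Oscillator and unit specifications for the synthetic cohort generator
#'
#' `oscSpec()` describes one band-limited oscillator: a cosine at `center_hz`
#' whose phase undergoes Wiener diffusion (so spectra have realistic width
#' and cross-region coherence below 1 is achievable), with optional coupling
#' hooks. Oscillators sharing a `shared_source_id` are driven by one common
#' phase realization; `shared_weight` w mixes the common drive with an
#' independent one as `w * cos(common) + sqrt(1 - w^2) * cos(own)`, which
#' controls cross-region coherence while preserving band power. `amp_mod`
#' multiplies the amplitude by `1 + depth * cos(phase_source - preferred)`
#' (a multiplicative envelope model of phase-amplitude coupling, matching
#' the analysis-side modulation index).
#'
#' `unitSpec()` describes one spiking unit: an inhomogeneous Poisson process
#' with rate `r0 * exp(kappa * cos(theta_band(t) - mu)) / I0(kappa)`, where
#' `theta_band` is the Hilbert phase of the band-passed region signal. The
#' von Mises normalization keeps the expected rate at `r0` for every kappa.
#'
#' @param region region label.
#' @param band band (one-row table or name resolved in [defaultBands()]).
#' @param center_hz oscillator frequency, inside the band.
#' @param amp amplitude in microvolts (tone power `amp^2 / 2`).
#' @param id oscillator id (used as an `amp_mod$phase_source` reference).
#' @param shared_source_id optional common-drive id.
#' @param shared_weight weight w of the common drive, in `[0, 1]`.
#' @param amp_mod optional list `(phase_source, depth, preferred_phase)`.
#' @param phase_diffusion Wiener phase diffusion rate, rad^2/s (default 5,
#'   about a 1 Hz linewidth).
#' @return A list of class `"OscSpec"` / `"UnitSpec"`.
#' @export
oscSpec <- function(region, band, center_hz, amp, id = NULL,
                    shared_source_id = NULL, shared_weight = 1,
                    amp_mod = NULL, phase_diffusion = 5) {
  if (is.character(band)) band <- .getBand(defaultBands(), band)
  if (center_hz < band$lo_hz || center_hz > band$hi_hz)
    stop("center_hz must lie inside the band")
  if (shared_weight < 0 || shared_weight > 1)
    stop("shared_weight must be in [0, 1]")
  if (!is.null(amp_mod)) {
    if (is.null(amp_mod$phase_source))
      stop("amp_mod needs a phase_source oscillator id")
    if (amp_mod$depth < 0 || amp_mod$depth > 1)
      stop("amp_mod depth must be in [0, 1]")
    if (is.null(amp_mod$preferred_phase)) amp_mod$preferred_phase <- 0
  }
  structure(list(region = region, band = band, center_hz = center_hz,
                 amp = amp,
                 id = if (is.null(id)) paste0(region, ".", band$name) else id,
                 shared_source_id = shared_source_id,
                 shared_weight = shared_weight, amp_mod = amp_mod,
                 phase_diffusion = phase_diffusion),
            class = "OscSpec")
}

#' @rdname oscSpec
#' @param base_rate_hz mean firing rate r0 > 0, Hz.
#' @param lock_band band whose phase modulates the rate.
#' @param kappa von Mises concentration, >= 0 (0 = homogeneous Poisson).
#' @param mu preferred firing phase, radians.
#' @param unit_id unit identifier.
#' @export
unitSpec <- function(region, base_rate_hz, lock_band, kappa = 0, mu = 0,
                     unit_id = NULL) {
  if (base_rate_hz <= 0) stop("base_rate_hz must be positive")
  if (kappa < 0) stop("kappa must be >= 0")
  if (is.character(lock_band)) lock_band <- .getBand(defaultBands(), lock_band)
  structure(list(region = region, base_rate_hz = base_rate_hz,
                 lock_band = lock_band, kappa = kappa, mu = mu,
                 unit_id = unit_id),
            class = "UnitSpec")
}

#' Simulate a multi-region LFP recording
#'
#' Each region is the sum of its oscillators plus `1/f^alpha` Gaussian noise
#' scaled to `sigma` microvolts. Oscillator phases follow
#' `2*pi*f*t + W(t)` with Wiener phase noise; oscillators sharing a
#' `shared_source_id` reuse one realization of the common phase path. Fully
#' reproducible from the seed.
#'
#' @param oscs list of [oscSpec()] objects.
#' @param duration_s recording length, seconds (>= 10 s recommended so that
#'   spectral estimates stabilize).
#' @param fs_hz sampling rate (default 1000).
#' @param noise list with `alpha` (spectral exponent, default 1) and `sigma`
#'   (noise SD in microvolts, default 20); `sigma = 0` disables noise.
#' @param regions region order of the output (default: order of first
#'   appearance in `oscs`).
#' @param seed integer seed.
#' @param subject_id,group recording metadata.
#' @return A [Recording-class] (no units; see [simulateSpikes()]).
#' @export
simulateLFP <- function(oscs, duration_s, fs_hz = 1000,
                        noise = list(alpha = 1, sigma = 20),
                        regions = NULL, seed = 1, subject_id = "sim",
                        group = "control") {
  for (o in oscs) {
    if (!inherits(o, "OscSpec")) stop("oscs must be a list of oscSpec()")
    if (o$center_hz >= fs_hz / 2)
      stop("oscillator frequency at or above the Nyquist frequency")
  }
  n <- round(duration_s * fs_hz)
  t <- (0:(n - 1)) / fs_hz
  if (is.null(regions))
    regions <- unique(vapply(oscs, `[[`, character(1), "region"))
  set.seed(seed)
  ## phase paths: one Wiener realization per shared source, one per oscillator
  wiener <- function(D) cumsum(rnorm(n, sd = sqrt(D / fs_hz)))
  shared_ids <- unique(unlist(lapply(oscs, `[[`, "shared_source_id")))
  shared_w <- lapply(setNames(shared_ids, shared_ids), function(id) {
    D <- oscs[[which(vapply(oscs, function(o)
      identical(o$shared_source_id, id), logical(1)))[1L]]]$phase_diffusion
    wiener(D)
  })
  phases <- list()   # full phase path per oscillator id
  own_w <- list()
  for (o in oscs) {
    own_w[[o$id]] <- wiener(o$phase_diffusion)
    base <- 2 * pi * o$center_hz * t
    phases[[o$id]] <- if (!is.null(o$shared_source_id)) {
      base + shared_w[[o$shared_source_id]]
    } else base + own_w[[o$id]]
  }
  lfp <- matrix(0, length(regions), n, dimnames = list(regions, NULL))
  for (o in oscs) {
    r <- match(o$region, regions)
    if (is.na(r)) stop("oscillator region '", o$region,
                       "' not in the region list")
    modf <- 1
    if (!is.null(o$amp_mod)) {
      src <- phases[[o$amp_mod$phase_source]]
      if (is.null(src))
        stop("amp_mod phase_source '", o$amp_mod$phase_source,
             "' does not name an oscillator")
      modf <- 1 + o$amp_mod$depth * cos(src - o$amp_mod$preferred_phase)
    }
    w <- o$shared_weight
    carrier <- if (!is.null(o$shared_source_id) && w < 1) {
      w * cos(phases[[o$id]]) +
        sqrt(1 - w^2) * cos(2 * pi * o$center_hz * t + own_w[[o$id]])
    } else cos(phases[[o$id]])
    lfp[r, ] <- lfp[r, ] + o$amp * modf * carrier
  }
  if (!is.null(noise) && noise$sigma > 0)
    for (r in seq_along(regions))
      lfp[r, ] <- lfp[r, ] +
        noise$sigma * .oneOverFNoise(n, fs_hz, noise$alpha)
  Recording(lfp = lfp, fs_hz = fs_hz, regions = regions,
            subject_id = subject_id, group = group)
}

#' Simulate phase-locked spike trains
#'
#' Inhomogeneous Poisson spikes by thinning: candidates are drawn from a
#' homogeneous Poisson process at the rate ceiling
#' `r0 * exp(kappa) / I0(kappa)` and accepted with probability
#' `r(t) / ceiling`, where
#' `r(t) = r0 * exp(kappa * cos(theta(t) - mu)) / I0(kappa)` and `theta(t)`
#' is the Hilbert phase of the band-passed region LFP (linearly interpolated
#' at candidate times). Thinning is exact, and the von Mises normalization
#' keeps the expected rate at `r0` for every kappa; `kappa = 0` reduces to a
#' homogeneous Poisson process.
#'
#' @param rec a [Recording-class] whose LFP contains the lock-band rhythm.
#' @param units list of [unitSpec()] objects.
#' @param seed integer seed.
#' @return The recording with the simulated [SpikeUnit-class]s appended.
#' @export
simulateSpikes <- function(rec, units, seed = 1) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs_hz
  dur <- duration(rec)
  set.seed(seed)
  ## phase paths per (region, band) actually needed
  phase_paths <- list()
  for (u in units) {
    key <- paste(u$region, u$lock_band$name)
    if (is.null(phase_paths[[key]]))
      phase_paths[[key]] <- .unwrap(bandpassAnalytic(
        lfpSignal(rec, u$region), fs, u$lock_band)$phase)
  }
  t_grid <- (seq_len(nSamples(rec)) - 1) / fs
  new_units <- list()
  for (k in seq_along(units)) {
    u <- units[[k]]
    if (u$kappa < 0) stop("kappa must be >= 0")
    uid <- if (is.null(u$unit_id)) {
      sprintf("unit_%02d", k + length(rec@units))
    } else u$unit_id
    i0k <- besselI(u$kappa, 0)
    rmax <- u$base_rate_hz * exp(u$kappa) / i0k
    n_cand <- rpois(1L, rmax * dur)
    cand <- sort(runif(n_cand, 0, dur))
    if (u$kappa == 0) {
      st <- cand
    } else {
      key <- paste(u$region, u$lock_band$name)
      phi <- .wrapPhase(approx(t_grid, phase_paths[[key]], xout = cand,
                               rule = 2)$y)
      rate <- u$base_rate_hz * exp(u$kappa * cos(phi - u$mu)) / i0k
      st <- cand[runif(n_cand) < rate / rmax]
    }
    st <- st[st < dur]
    new_units[[length(new_units) + 1L]] <-
      SpikeUnit(uid, u$region, unique(st))
  }
  rec@units <- c(rec@units, new_units)
  validObject(rec)
  rec
}

#' Plant co-activation patterns into a recording
#'
#' Ground-truth generator for the barcode method: during each pattern's
#' activation epochs, the band-limited components of the loaded
#' `(region, band)` channels are co-modulated by a common strictly positive
#' slow latent time course `g(t)` (lognormal: the exponential of low-pass
#' filtered Gaussian noise, median 1), scaled by the channel loadings:
#' `x <- x + bandpass(x, band) * loading * g(t)` inside the epochs. The
#' latent courses are returned for recovery scoring. A zero-loading pattern
#' leaves the recording untouched bitwise.
#'
#' @param rec a [Recording-class].
#' @param patterns list of patterns, each a list with `name`, `loadings`
#'   (named numeric over `region.band` channels) and `epochs` (data.frame
#'   with `start_s`, `end_s`).
#' @param seed integer seed for the latent courses.
#' @param bands band table (default [defaultBands()]).
#' @param latent_cut_hz low-pass cutoff of the latent course (default 0.5).
#' @return List with `recording` (modified), `latents` (matrix
#'   `n_patterns x n_samples`) and `patterns`.
#' @export
plantBarcodePatterns <- function(rec, patterns, seed = 1,
                                 bands = defaultBands(),
                                 latent_cut_hz = 0.5) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs_hz
  n <- nSamples(rec)
  channels <- as.vector(outer(rec@regions, bands$name, paste, sep = "."))
  for (p in patterns)
    if (!all(names(p$loadings) %in% channels))
      stop("pattern loads unknown channel(s): ",
           paste(setdiff(names(p$loadings), channels), collapse = ", "))
  set.seed(seed)
  bf <- signal::butter(2, latent_cut_hz / (fs / 2), type = "low")
  latents <- matrix(0, length(patterns), n)
  for (k in seq_along(patterns)) {
    g <- signal::filtfilt(bf, rnorm(n))
    latents[k, ] <- exp(0.75 * g / sd(g))
  }
  ## band-pass each loaded channel once, then apply the summed modulation
  lfp <- rec@lfp
  gains <- list()   # channel -> total modulation gain over time
  for (k in seq_along(patterns)) {
    p <- patterns[[k]]
    lam <- p$loadings[p$loadings != 0]
    if (!length(lam)) next
    mask <- rep(0, n)
    for (r in seq_len(nrow(p$epochs))) {
      i0 <- floor(p$epochs$start_s[r] * fs) + 1L
      i1 <- min(floor(p$epochs$end_s[r] * fs), n)
      if (i1 >= i0) mask[i0:i1] <- 1
    }
    for (ch in names(lam)) {
      add <- lam[[ch]] * latents[k, ] * mask
      gains[[ch]] <- if (is.null(gains[[ch]])) add else gains[[ch]] + add
    }
  }
  for (ch in names(gains)) {
    parts <- strsplit(ch, ".", fixed = TRUE)[[1L]]
    reg <- parts[1L]
    band <- .getBand(bands, parts[2L])
    r <- match(reg, rec@regions)
    bp <- bandpassAnalytic(lfp[r, ], fs, band)$filtered
    lfp[r, ] <- lfp[r, ] + bp * gains[[ch]]
  }
  rec@lfp <- lfp
  list(recording = rec, latents = latents, patterns = patterns)
}
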