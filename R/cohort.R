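## Frozen calibration constants for the synthetic cohort defaults. The
## group-level targets are the printed anchors of the study design (control
## vs lesion band power in dB, coherence magnitudes, PAC modulation index,
## firing rates and locking): the constants below were found once by a
## simulation sweep against those targets and then frozen; they are not
## fitted at run time.
.cohortCalib <- list(
  noise_sigma = 12, noise_alpha = 1,
  ## oscillator amplitudes (microvolts), control group
  amp = c(OB.theta = 82, OB.beta = 10, OB.gamma = 12.85,
          aPC.theta = 65, aPC.beta = 10, aPC.gamma = 22,
          LEC.theta = 75, LEC.beta = 10, LEC.gamma = 9),
  ## lesion amplitude multipliers (band-power anchors: OB gamma -2.3 dB,
  ## OB theta -2.8 dB, aPC theta -2.8 dB, LEC theta +2.7 dB)
  lesion_amp_mult = c(OB.theta = 0.71, OB.beta = 1, OB.gamma = 0.82,
                      aPC.theta = 0.70, aPC.beta = 1, aPC.gamma = 1,
                      LEC.theta = 1.39, LEC.beta = 1, LEC.gamma = 1),
  ## shared-drive weights (applied on the aPC/LEC side; the OB oscillator
  ## carries the common drive): OB-aPC gamma coherence 0.62 vs 0.40,
  ## OB-LEC theta coherence 0.27 vs 0.43
  shared_w_gamma = c(control = 0.91, lesion = 0.59),
  shared_w_theta = c(control = 0.27, lesion = 0.46),
  ## multiplicative PAC depth (OB theta phase -> aPC gamma amplitude):
  ## modulation index 0.0034 vs 0.0017
  pac_depth = c(control = 0.235, lesion = 0.165),
  ## units: doubled lesion rate; gamma locking reduced ~75% in mean
  ## resultant length, theta locking preserved
  rate_hz = c(control = 5, lesion = 10),
  kappa_gamma = c(control = 2.0, lesion = 0.35),
  kappa_theta = c(control = 1.0, lesion = 1.0),
  ## NOR exploration-time means (s): control DI ~ 0.45, lesion DI ~ -0.03
  nor_novel_mean = c(control = 3.0, lesion = 1.95),
  nor_familiar_mean = c(control = 1.15, lesion = 2.05),
  ## gain applied to the OB theta component during novel epochs per unit of
  ## planted effect size d on the OB theta dB feature
  gain_per_d = 0.027,
  ## per-subject lognormal amplitude jitter (SD of log amplitude)
  subject_jitter = 0.04,
  osc_centers = c(theta = 7, beta = 25, gamma = 60),
  ## per-band Wiener phase diffusion (rad^2/s): linewidths of roughly 0.6,
  ## 3 and 19 Hz, so each rhythm fills a realistic share of its band
  phase_diffusion = c(theta = 4, beta = 20, gamma = 120))

#' Specify a synthetic two-group cohort
#'
#' The generator's defaults encode the study conditions: 8 subjects per
#' group, 120-s recordings at 1000 Hz, three regions (OB, aPC, LEC) with
#' theta/beta/gamma oscillators riding on 1/f noise, lesion-group effects in
#' the direction and magnitude of the printed anchors (reduced OB gamma and
#' OB/aPC theta power, raised LEC theta power, reduced OB-aPC gamma
#' coherence and phase-amplitude coupling, raised OB-LEC theta coherence,
#' doubled firing rate with selectively degraded gamma phase locking), 20
#' behavioral epochs per condition with control-only novelty preference, and
#' a configurable neural-behavior linkage: novel epochs boost the OB theta
#' envelope so the OB theta power feature separates conditions by `effect_d`
#' within-class standard deviations (0 = null world).
#'
#' @param n_per_group subjects per group (default 8).
#' @param duration_s recording length per subject, seconds (default 120).
#' @param fs_hz sampling rate (default 1000).
#' @param n_epochs_per_condition behavioral epochs per condition (default 20).
#' @param effect_d planted effect size of the novel-epoch OB theta shift:
#'   either one number used for both groups or a named vector
#'   `c(control = , lesion = )`. The default plants the linkage in controls
#'   only (`c(control = 1.5, lesion = 0)`), so novelty is decodable from OB
#'   theta in controls and abolished in the lesion group; 0 gives the null
#'   world.
#' @param paradigm `"nor"` (novel-object epochs) or `"odor"`
#'   (habituation-dishabituation presentations).
#' @param barcode_patterns optional list of patterns for
#'   [plantBarcodePatterns()]; `NULL` plants the default gamma co-activation
#'   pattern during novel epochs (control loading 0.25, lesion 0.1);
#'   `list()` plants none.
#' @param n_units_per_subject OB units per subject (half gamma-locked, half
#'   theta-locked; default 4).
#' @param seed integer master seed.
#' @return A list of class `"CohortSpec"`.
#' @export
cohortSpec <- function(n_per_group = 8, duration_s = 120, fs_hz = 1000,
                       n_epochs_per_condition = 20,
                       effect_d = c(control = 1.5, lesion = 0),
                       paradigm = c("nor", "odor"), barcode_patterns = NULL,
                       n_units_per_subject = 4, seed = 1) {
  paradigm <- match.arg(paradigm)
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (duration_s < 10) stop("duration_s must be >= 10 s")
  if (length(effect_d) == 1L)
    effect_d <- c(control = unname(effect_d), lesion = unname(effect_d))
  if (!all(c("control", "lesion") %in% names(effect_d)))
    stop("effect_d must be one number or a named control/lesion vector")
  structure(list(n_per_group = n_per_group, duration_s = duration_s,
                 fs_hz = fs_hz,
                 n_epochs_per_condition = n_epochs_per_condition,
                 effect_d = effect_d, paradigm = paradigm,
                 barcode_patterns = barcode_patterns,
                 n_units_per_subject = n_units_per_subject,
                 seed = as.integer(seed), calib = .cohortCalib),
            class = "CohortSpec")
}

## oscillator list for one subject; jitter multiplies all amplitudes of a
## subject by one lognormal factor per channel
.subjectOscs <- function(group, calib, jitter_mult) {
  bands <- defaultBands()
  oscs <- list()
  for (reg in c("OB", "aPC", "LEC")) {
    for (b in bands$name) {
      ch <- paste(reg, b, sep = ".")
      amp <- calib$amp[[ch]] * jitter_mult[[ch]]
      if (group == "lesion") amp <- amp * calib$lesion_amp_mult[[ch]]
      shared <- NULL
      w <- 1
      if (b == "gamma" && reg %in% c("OB", "aPC")) {
        shared <- "src_gamma_ob_apc"
        w <- if (reg == "aPC") calib$shared_w_gamma[[group]] else 1
      }
      if (b == "theta" && reg %in% c("OB", "LEC")) {
        shared <- "src_theta_ob_lec"
        w <- if (reg == "LEC") calib$shared_w_theta[[group]] else 1
      }
      amp_mod <- NULL
      if (reg == "aPC" && b == "gamma")
        amp_mod <- list(phase_source = "OB.theta",
                        depth = calib$pac_depth[[group]],
                        preferred_phase = 0)
      oscs[[ch]] <- oscSpec(reg, b, calib$osc_centers[[b]], amp, id = ch,
                            shared_source_id = shared, shared_weight = w,
                            amp_mod = amp_mod,
                            phase_diffusion = calib$phase_diffusion[[b]])
    }
  }
  oscs
}

## sequential behavioral epochs; durations jittered, whole schedule rescaled
## into the recording if needed (the discrimination index is scale-invariant)
.norEvents <- function(n_per_cond, duration_s, novel_mean, familiar_mean) {
  conds <- rep(c("familiar", "novel"), n_per_cond)
  conds <- conds[sample(length(conds))]
  durs <- ifelse(conds == "novel",
                 pmax(1, rnorm(length(conds), novel_mean,
                               0.2 * novel_mean)),
                 pmax(1, rnorm(length(conds), familiar_mean,
                               0.2 * familiar_mean)))
  gaps <- runif(length(conds), 0.3, 0.7)
  starts <- 1 + cumsum(c(0, durs[-length(durs)] + gaps[-length(gaps)]))
  ends <- starts + durs
  total <- ends[length(ends)] + 1
  if (total > duration_s) {
    sc <- (duration_s - 2) / total
    starts <- 1 + (starts - 1) * sc
    ends <- 1 + (ends - 1) * sc
  }
  k <- ave(seq_along(conds), conds, FUN = seq_along)
  EventTable(data.frame(
    epoch_id = sprintf("%s_%02d", conds, k),
    label = paste0("exploration_", conds),
    start_s = starts, end_s = ends, condition = conds,
    stringsAsFactors = FALSE))
}

.odorEvents <- function(duration_s, group) {
  ## 3 odors x 3 presentations; sniffing decays within an odor and rebounds
  ## at a switch for controls but not for the lesion group
  base <- if (group == "control") {
    c(6.0, 3.5, 2.0, 5.5, 3.0, 1.8, 5.0, 2.8, 1.7)
  } else {
    c(5.5, 3.4, 2.2, 2.5, 2.3, 2.1, 2.4, 2.2, 2.1)
  }
  sniff <- pmax(0.4, base + rnorm(9, sd = 0.25))
  odor <- rep(paste0("odor", 1:3), each = 3)
  trial <- rep(1:3, 3)
  cond <- ifelse(trial == 1 & odor != "odor1", "novel", "habituation")
  slot_s <- (duration_s - 4) / 9
  starts <- 2 + (seq_len(9) - 1) * slot_s
  ends <- starts + pmin(sniff, slot_s - 0.5)
  EventTable(data.frame(
    epoch_id = sprintf("%s_p%d", odor, trial),
    label = sprintf("%s_trial%d", odor, trial),
    start_s = starts, end_s = ends, condition = cond,
    stringsAsFactors = FALSE))
}

#' Simulate a two-group cohort with planted ground truth
#'
#' Generates `n_per_group` recordings per group with the effects described
#' in [cohortSpec()], plus per-subject event tables, and records every
#' planted parameter in a `ground_truth` list (oscillator amplitudes and
#' shared-drive weights, PAC depths, unit rates and concentrations, barcode
#' pattern loadings and latent courses, the novel-epoch feature gain, and
#' the exploration-time model) so downstream recovery tests never have to
#' re-derive them. Deterministic given the seed.
#'
#' @param spec a `"CohortSpec"`.
#' @return List with `subjects` (each: `recording`, `events`) and
#'   `ground_truth`.
#' @export
simulateCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  calib <- spec$calib
  bands <- defaultBands()
  subjects <- list()
  gt_subjects <- list()
  idx <- 0L
  for (group in c("control", "lesion")) {
    for (s in seq_len(spec$n_per_group)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", group, s)
      sseed <- .subSeed(spec$seed, idx)
      set.seed(sseed)
      jit <- exp(rnorm(9, sd = calib$subject_jitter))
      names(jit) <- names(calib$amp)
      oscs <- .subjectOscs(group, calib, jit)
      rec <- simulateLFP(oscs, spec$duration_s, spec$fs_hz,
                         noise = list(alpha = calib$noise_alpha,
                                      sigma = calib$noise_sigma),
                         regions = c("OB", "aPC", "LEC"),
                         seed = .subSeed(sseed, 1L), subject_id = sid,
                         group = group)
      set.seed(.subSeed(sseed, 2L))
      events <- if (spec$paradigm == "nor") {
        .norEvents(spec$n_epochs_per_condition, spec$duration_s,
                   calib$nor_novel_mean[[group]],
                   calib$nor_familiar_mean[[group]])
      } else .odorEvents(spec$duration_s, group)
      ## neural-behavior linkage: boost the OB theta component in novel epochs
      gain <- spec$effect_d[[group]] * calib$gain_per_d
      if (gain != 0) {
        ev <- events@events
        nov <- ev[ev$condition == "novel", , drop = FALSE]
        if (nrow(nov)) {
          mask <- rep(0, nSamples(rec))
          for (r in seq_len(nrow(nov))) {
            i0 <- floor(nov$start_s[r] * spec$fs_hz) + 1L
            i1 <- min(floor(nov$end_s[r] * spec$fs_hz), nSamples(rec))
            mask[i0:i1] <- 1
          }
          ob <- match("OB", rec@regions)
          bp <- bandpassAnalytic(rec@lfp[ob, ], spec$fs_hz,
                                 "theta")$filtered
          rec@lfp[ob, ] <- rec@lfp[ob, ] + bp * gain * mask
        }
      }
      ## barcode co-activation pattern(s)
      patterns <- spec$barcode_patterns
      if (is.null(patterns)) {
        load <- if (group == "control") 0.25 else 0.1
        ev <- events@events
        nov <- ev[ev$condition == "novel", c("start_s", "end_s")]
        patterns <- list(list(
          name = "gamma_coact",
          loadings = c(OB.gamma = load, aPC.gamma = load),
          epochs = nov))
      }
      latents <- NULL
      if (length(patterns)) {
        pl <- plantBarcodePatterns(rec, patterns, seed = .subSeed(sseed, 3L),
                                   bands = bands)
        rec <- pl$recording
        latents <- pl$latents
      }
      ## spiking units: half gamma-locked, half theta-locked, in the OB
      n_units <- spec$n_units_per_subject
      units <- vector("list", n_units)
      for (k in seq_len(n_units)) {
        gamma_unit <- k <= ceiling(n_units / 2)
        units[[k]] <- unitSpec(
          "OB", calib$rate_hz[[group]],
          if (gamma_unit) "gamma" else "theta",
          kappa = if (gamma_unit) calib$kappa_gamma[[group]] else
            calib$kappa_theta[[group]],
          mu = 0, unit_id = sprintf("%s_u%02d_%s", sid, k,
                                    if (gamma_unit) "gamma" else "theta"))
      }
      rec <- simulateSpikes(rec, units, seed = .subSeed(sseed, 4L))
      subjects[[sid]] <- list(recording = rec, events = events)
      gt_subjects[[sid]] <- list(
        group = group, amp_jitter = jit,
        units = lapply(units, function(u)
          list(unit_id = u$unit_id, base_rate_hz = u$base_rate_hz,
               lock_band = u$lock_band$name, kappa = u$kappa, mu = u$mu)),
        patterns = patterns, latents = latents)
    }
  }
  list(subjects = subjects,
       ground_truth = list(calib = calib, spec = spec[names(spec) != "calib"],
                           subjects = gt_subjects))
}
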