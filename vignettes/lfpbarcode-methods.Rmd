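---
title: "Cross-regional oscillation analysis with co-activation barcodes: models and methods"
author: "lfpbarcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-regional oscillation analysis with co-activation barcodes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpbarcode)
```

## Scope

`lfpbarcode` analyses simultaneous local field potential (LFP) and
single-unit recordings from the rodent olfactory network — olfactory bulb
(OB), anterior piriform cortex (aPC) and lateral entorhinal cortex (LEC) —
the setting in which cross-regional oscillatory "dysrhythmias" accompany
Parkinsonian cognitive decline. The package covers five analysis families
(spectral, cross-frequency and spike-field coupling, co-activation barcodes,
population decoding/forecasting, behavioral indices) plus a synthetic cohort
generator that plants known structure into every one of them, so each stage
can be validated against ground truth. This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic tests
do and do not establish about real recordings.

Frequency bands follow the olfactory-electrophysiology convention used
throughout: theta 3–12 Hz, beta 15–35 Hz, gamma 36–95 Hz
(`defaultBands()`); LFPs are sampled at 1000 Hz.

## Spectral analysis

`welchPSD()` averages Hann-windowed periodograms (2-s segments, 50%
overlap by default, one-sided density scaling). The defaults resolve the
3-Hz theta edge with 0.5-Hz resolution. No detrending or line-noise notch
is applied by default — 50 Hz sits inside the gamma band, so a notch is a
deliberate user decision, not something done silently.

`bandPowerDb()` integrates the PSD with the trapezoid rule over the bins
whose centers fall in the closed band, and reports decibels **re 1 µV² of
band-integrated power**. The literature this package serves prints absolute
dB values without stating a reference; under our convention only
*differences* between conditions or groups are scientifically meaningful,
and the simulator is calibrated so its absolute levels land near the
printed anchor values. An identically zero signal yields `-Inf` with a
`zero_signal` flag rather than an error.

`bandCoherence()` forms Welch auto- and cross-spectra with the same
segmentation and reports magnitude-squared coherence per bin. The per-band
summary is the mean of `sqrt(msc)` — coherence *magnitude* — because the
printed values this field reports (≈0.27–0.62) correspond to magnitude,
not squared coherence; `summary = "msc"` switches conventions. Fewer than 8
segments inflates coherence substantially (bias ≈ 1/n segments), so such
results carry a `high_bias` flag and a warning.

`maxXCorr()` is the coefficient-normalized time-lagged cross-correlation
(means removed, autocorrelation at lag 0 equal to 1); the absolute maximum
of the curve is the coupling-strength index, so an inverted signal scores
identically. Exact ties break toward lag 0, then toward the negative lag —
a deterministic rule so results do not depend on scan order.

## Band-limited phase, PAC, and spike-field coupling

`bandpassAnalytic()` applies a 4th-order Butterworth per pass with
forward–backward filtering (zero phase by construction) and takes the
analytic signal via the frequency-domain Hilbert transform. The phase
convention is **cosine phase**: 0 at a local peak. This affects only how
preferred phases are reported.

`pacMI()` is the Tort-style modulation index: the fast band's amplitude is
binned by the slow band's phase (18 bins by default), the profile is
normalized to sum 1, and MI = KL(profile ‖ uniform)/log(n bins) ∈ [0, 1].
The estimator is adopted because modulation-index values of a few
thousandths — the magnitude printed in this literature — are characteristic
of this normalization; a mean-vector-length variant is available via
`method = "mvl"`. Phase–amplitude coupling in the simulator is generated
multiplicatively on the amplitude envelope, `1 + m·cos(φ_slow − φ0)`,
matching the analysis-side estimator, and the generative profile has a
closed-form expected MI used as the test oracle. An empty phase bin raises
an error advising a longer signal rather than returning a biased value.

`spikePhaseLocking()` aligns each spike to the band phase by linear
interpolation of the *unwrapped* phase (interpolating wrapped phase across
the ±π seam produces spurious phases). It reports the mean resultant length
(mrl), circular mean, and the closed-form Rayleigh approximation
`p = exp(sqrt(1 + 4n + 4(n² − R²)) − (1 + 2n))`. `classifyLocked()` calls a
unit phase-locked when the Rayleigh p-value is below α = 0.05 **and** at
least 20 spikes support the estimate — the low-n guard protects against the
positive small-sample bias of the mrl. The phase reference defaults to the
unit's own region's LFP; any other region's signal can be passed instead.
Spike-triggered averages (`spikeTriggeredAverage()`) drop spikes whose
window would cross a recording edge and can report the band power of the
average waveform (single Hann periodogram — the window is far too short for
Welch averaging).

## The barcode method

The barcode pipeline extracts recurring cross-regional oscillatory
co-activation motifs:

1. **Masked EMD** (`maskedEMD()`). Plain empirical mode decomposition mixes
   modes; adding a known sinusoidal mask pins the extrema spacing. For each
   mask frequency (an octave ladder `fs/4, fs/8, …` by default, descending),
   the signal plus a mask at 4 equispaced phases is sifted, the mask
   subtracted, the four results averaged, and the resulting intrinsic mode
   function removed before recursing. Sifting stops when the mean envelope
   carries under `1e-4` of the component energy (an SD-style criterion);
   envelopes are natural cubic splines through the extrema with mirrored
   boundary knots. Because every step is a subtraction, the IMF stack plus
   residual reconstructs the input to floating-point accuracy — an invariant
   the tests enforce at 1e-6 relative error. Mask amplitude defaults to 2
   residual SDs.
2. **Band assignment** (`selectIMFs()`): an IMF joins the band containing
   its amplitude-weighted mean instantaneous frequency (edges trimmed 2%
   where the Hilbert transform is unreliable); IMFs falling between bands
   are dropped; several IMFs in one band have their envelopes summed. This
   rule is deterministic and bandwise-complete. A band left empty gets a
   zero channel, a warning and a flag.
3. **Amplitude matrix** (`amplitudeMatrix()`): channels ordered
   region-major, each divided by its standard deviation. The mean is *not*
   removed — envelopes are non-negative, and the ICA step centers its own
   features.
4. **Co-participation features** (`coparticipation()`): non-overlapping
   250-ms windows ("sampling every 250 ms" read as a 4-Hz sampling of
   co-participation; window means rather than point samples reduce
   variance); per window, the outer product of the channel-mean vector,
   vectorized over the upper triangle *including the diagonal* — the
   self-terms carry within-channel power and discarding them would lose it.
5. **ICA** (`fitBarcodes()`): features centered, PCA-whitened to
   `n_barcodes` dimensions (8 by default; the figure galleries this method
   produces show at least 7 motifs and the exact count is a free choice),
   then fixed-point ICA with the log-cosh contrast and deflation — chosen
   for determinism and per-component convergence diagnostics. The seed only
   sets the orthogonal initialization; the same seed and data give
   bit-identical fits. Non-convergence is an error, not a silent result.

A fitted `BarcodeModel` carries two matrices per barcode:

* the **unmixing row** `W` (unit-norm, largest-magnitude element positive)
  — the filter that *extracts* the component from standardized features;
* the **signature** — the unit-norm ICA *mixing* direction mapped to
  feature space, oriented so its dominant co-participation feature
  co-activates. The signature is the pattern the component imprints on the
  features; it is what the barcode grid graphics render, and what recovery
  tests compare against planted ground truth. Unmixing row and signature
  coincide only when components do not overlap in feature space.

**Strength time series.** `barcodeStrength()` projects the raw
(non-standardized) co-participation vectors onto each barcode, one value
per 250-ms window. The projection uses the *signature* by default. The
distinction matters: on raw features, whose per-feature scales differ from
the standardized space the unmixing was learned in, the unmixing
projection's response to its own component is a sign-indefinite quantity
that in simulation failed to track planted activations in roughly a third
of runs, while the signature projection's own-component response is
non-negative by construction (up to the documented orientation) and tracked
planted activations essentially perfectly. The literal unmixing
projection remains available via `use = "unmixing"`.

`barcodeScore()` quantifies behavior alignment as the ROC area
discriminating window-mean strength between positive-condition epochs
(e.g. novel) and contrast epochs: 0.5 is uninformative, 1 means strength is
higher in every positive window. The source literature never defines its
"score" formula; this package states its own definition prominently and
uses it consistently.

## Decoding and forecasting

`buildTrialFeatures()` computes one feature vector per behavioral epoch.
Epoch band powers use a **fixed** 0.5-s Welch segment regardless of epoch
duration: with per-epoch-adaptive segments, spectral-leakage bias varies
with epoch length, and because novel-object bouts are systematically longer
than familiar-object bouts, epoch duration masqueraded as a power
difference (a spurious ~0.45 SD condition effect in the null world; fixed
resolution reduces it to ~0.09). Epoch coherence features are tagged as
biased features for decoding, not coherence estimates, since short epochs
give few Welch segments.

`svmDecode()` implements the population-decoding protocol: per iteration,
subjects are split 80/20 within each group (animal-wise — no trial of a
held-out animal ever reaches training), training classes are balanced by
random down-sampling, features are z-scored on training statistics, a
linear SVM (C = 1, fixed for reproducibility) is fit, and accuracy is
pooled over held-out trials. The default 500 iterations and 100 label
shuffles mirror the protocol this analysis reproduces. The chance interval
is `0.5 ± 2 SD` of null mean accuracies with labels permuted *within*
subject — a stricter null than global shuffling because it preserves each
animal's class counts and subject structure — and a result is "significant"
when the mean accuracy falls outside it. Each shuffle runs the full
decoding procedure; balancing is redrawn every iteration.

`forecastOutcome()` is the early-to-late forecasting scaffold: a random
forest (500 trees) maps early oscillatory features (one row per subject) to
a later binary outcome, with a subject-level stratified 80/20 split, test
AUC from held-out class probabilities, and confusion matrices at the 0.5
threshold. A numeric later outcome (a discrimination index) is binarized as
`di < threshold`; the default threshold 0 calls an animal impaired when it
no longer prefers the novel object at all, and is configurable (the
acceptance script uses 0.15, the midpoint between the simulated groups'
discrimination-index distributions).

The paper-scale decoding/forecasting accuracies (e.g. ~79% or ~90%) are
properties of in-lab animal recordings that are not deposited; the package
reproduces the *procedures* and validates them on synthetic cohorts where
chance calibration and power are known by construction.

## The synthetic cohort generator

`simulateCohort()` generates the study conditions: two groups (control,
lesion) of 8 subjects, 120-s three-region recordings at 1000 Hz, 20
behavioral epochs per condition. Each region is a sum of theta/beta/gamma
oscillators over `1/f` noise (spectrally shaped Gaussian noise, flattened
below 1 Hz so the process stays stationary). Oscillator phases follow
Wiener diffusion rather than fixed-phase sinusoids, so spectra have
realistic width and cross-region coherence below 1 is achievable; the
per-band diffusion rates (theta/beta/gamma linewidths ≈ 0.6/3/19 Hz) were
chosen because a narrow gamma line cannot produce band-mean coherence of
0.4–0.6 across the 36–95 Hz band. Cross-region coherence is controlled by
a shared phase drive carried entirely by the OB oscillator, with the
partner region (aPC for gamma, LEC for theta) mixing the common and an
independent drive; putting the weight on one side keeps the OB theta phase
identical to the common phase, which is essential because that same phase
drives the planted phase–amplitude coupling. Spikes are inhomogeneous
Poisson by exact thinning against the von Mises rate ceiling
`r0·exp(κ)/I0(κ)`, which preserves the mean rate for every κ.

The lesion-group defaults encode the direction *and magnitude* anchors of
the study design as simulation targets: OB gamma power 21.49 → 19.16 dB,
OB theta 34.84 → 32.02 dB, aPC theta 33.07 → 30.26 dB, LEC theta
34.49 → 37.16 dB, OB–aPC gamma coherence 0.62 → 0.40, OB–LEC theta
coherence 0.27 → 0.43, phase–amplitude coupling MI 0.0034 → 0.0017, doubled
spontaneous firing rate, and gamma phase locking reduced ~75% in mean
resultant length with theta locking preserved. These are *generator
defaults*, not acceptance targets: the calibration constants behind them
(oscillator amplitudes, shared-drive weights, coupling depths,
concentrations) were found once by a simulation sweep against those anchors
and frozen in the package source; nothing is fitted at run time.

Behavior: novel-object exploration bouts are drawn so the control group's
discrimination index sits near 0.45 and the lesion group's near 0 (the
late-stage anchors), with all epochs at least 1 s so epoch spectra are
estimable; the whole schedule is rescaled into the recording if needed (the
discrimination index is scale-invariant). The odor paradigm
(`paradigm = "odor"`) produces three presentations of each of three odors
with within-odor sniffing decay and a sniffing rebound at odor switches in
controls only. The behavior–neural linkage boosts the OB theta component
during novel epochs so the epoch-level OB theta power feature separates
conditions by `effect_d` within-class standard deviations; the gain-per-d
constant was calibrated once on the default conditions (planted d = 1.5
realizes ≈ 1.57). By default the linkage is planted in controls only, so
novelty is decodable from control OB theta and abolished in the lesion
group; `effect_d = 0` yields the null world used for chance calibration.

`plantBarcodePatterns()` co-modulates the band-limited components of loaded
(region, band) channels by a common strictly positive slow latent course —
the exponential of 0.5-Hz-low-passed Gaussian noise, median 1 — inside
activation epochs, and returns the latent courses for recovery scoring. The
default cohort plants one gamma co-activation pattern (OB+aPC) during novel
epochs with loading 0.25 in controls and 0.1 in the lesion group: gamma
co-activation during cognition, attenuated by the lesion. Every planted
parameter lands in the returned `ground_truth`, so downstream recovery
tests never re-derive it.

What the generator does **not** emulate: respiration-locked sniffing
dynamics, conductance-based biophysics, electrode artifacts and line noise,
non-stationary behavioral state changes, volume conduction, or spike
sorting errors. Tests passing on this generator show the *estimators and
procedures* are correct and calibrated — not that real recordings satisfy
the generative assumptions.

## Numerical and design choices

* Time runs in seconds; sample indices are `floor(t·fs)` on half-open
  intervals `[start, end)`, so adjacent epoch slices tile a recording with
  no duplicated or lost samples, and a spike at exactly the epoch end
  belongs to the next epoch.
* Signals live in HDF5 (dataset `/lfp`, root attributes, one group per
  unit); events live in plain CSV with the exact header
  `epoch_id,label,start_s,end_s,condition` so behavioral re-labeling never
  touches signal files. Validation is eager at load so errors carry file
  context. A lighter container than NWB was chosen deliberately; the layout
  is documented bit-exactly in `?readRecording`.
* In-band frequency-bin selection uses bin centers within the closed band —
  deterministic across platforms.
* All pipeline stage seeds derive from one master seed by a fixed splitting
  rule; identical seeds give bitwise-identical cohorts, barcodes and
  decoding results.
* Degenerate inputs fail loudly: constant signals in `maxXCorr()`, empty
  phase bins in `pacMI()`, zero-variance amplitude channels, ICA
  non-convergence, too-short signals for filtering or Welch averaging.

## Problem sizes in the test suite

The packaged tests validate each stage at sizes chosen to make the oracles
sharp while keeping a full run practical on a laptop: 600-s recordings for
the spike-locking Bessel-ratio oracle, 100-s signals for the
coherence–SNR law and PAC depth sweeps (20 seeds), 100 random 10-s 1/f
signals for EMD completeness, ten 300-s three-region recordings with three
planted patterns for barcode recovery, decoding calibration on 100
null-world trial tables and 50 powered cohorts with the cross-validation
count scaled from 500 to 50, and a 16-subject, 120-s cohort for the
direction-of-effect integration test. The decoding calibration uses the
trial-level generator (`simulateTrialTable()`), which reproduces the
subjects/trials/effect-size structure of the cohort linkage without paying
for signal synthesis in each of the hundreds of replicate datasets; the
LFP-level linkage itself is validated separately.

## Known limitations

* The dB reference and the coherence summary convention are package
  choices; absolute levels are only comparable within these conventions.
* Masked EMD can split one tone across two adjacent IMFs near mask-ladder
  boundaries; band assignment re-merges such splits through envelope
  summation, but IMF counts are not meaningful per se.
* The mrl-based "consistency" of spike-field locking is positively biased
  below ~20 spikes; such units are flagged and excluded from
  classification.
* Barcode polarity is identifiable only up to the documented orientation
  conventions; comparisons across fits should match components by
  signature cosine (Hungarian assignment) rather than index.
* The Rayleigh p-value is a closed-form approximation; for very small n the
  Monte Carlo surrogate null (`p_method = "surrogate"`) should be
  preferred.
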