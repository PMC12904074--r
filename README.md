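# lfpbarcode

Cross-regional neural-oscillation analysis for multi-site LFP + spike
recordings from the rodent olfactory network — olfactory bulb (OB),
anterior piriform cortex (aPC) and lateral entorhinal cortex (LEC) — the
circuit whose frequency-specific "dysrhythmias" track Parkinsonian
olfactory and cognitive decline. The package is written for
electrophysiologists who need the full analysis chain from raw signals to
group-level statistics, with every stage testable against planted ground
truth.

## What it computes

**Spectral.** Welch power spectral density, band power in dB
(theta 3–12 Hz, beta 15–35 Hz, gamma 36–95 Hz), band-averaged
cross-spectral coherence `|S_xy|² / (S_xx·S_yy)` (summarized as coherence
magnitude per band), and the normalized time-lagged cross-correlation whose
absolute maximum indexes coupling strength.

**Coupling.** Zero-phase band-pass + Hilbert phase/amplitude; theta→gamma
phase–amplitude coupling via the Tort modulation index
`MI = KL(amplitude-by-phase profile ‖ uniform) / log(n_bins)` with
comodulograms; spike-phase locking (mean resultant length
`mrl = |mean e^{iφ}|`, Rayleigh non-uniformity test, a unit counts as
phase-locked when p < 0.05 with ≥ 20 spikes); spike-triggered LFP averages.

**Barcodes.** The co-activation "barcode" method: masked empirical mode
decomposition per region, band-assigned Hilbert amplitude envelopes
standardized by their SD, 250-ms co-participation vectors (upper triangle
of the outer product of windowed channel amplitudes), and fixed-point ICA
(log-cosh, deflation) whose components are the barcodes — each with a
detector (unmixing row) and a signature (feature-space pattern). Dotting
barcodes with the raw-amplitude co-participation series gives per-motif
strength over time; `barcodeScore()` is the ROC area aligning strength with
behavioral epochs.

**Decoding & forecasting.** Linear-SVM decoding of familiar-vs-novel trials
with animal-wise 80/20 splits, training-class balancing, 500
cross-validation iterations and a chance interval `0.5 ± 2·SD` of null
accuracies from 100 within-subject label shuffles; random-forest
forecasting of later behavioral impairment from early oscillatory features
(test AUC + confusion matrices).

**Behavior.** Discrimination index
`di = (t_novel − t_familiar) / (t_novel + t_familiar)`, per-condition
exploration totals, habituation–dishabituation curves.

**Synthetic cohorts.** `simulateCohort()` generates two-group (control vs
lesion) cohorts with planted, recoverable structure: 1/f noise plus
phase-diffusing band oscillators, controllable cross-region coherence and
phase–amplitude coupling, von Mises phase-locked Poisson spikes, planted
co-activation patterns, and behavior–neural linkage with known effect size.
Every planted parameter is returned as ground truth, and the lesion-group
defaults encode the canonical anchors (reduced OB gamma power and OB–aPC
gamma coherence, raised LEC theta power and OB–LEC theta coherence, halved
PAC, doubled firing rate, ~75% lower gamma locking, abolished novelty
preference and decoding).

## Worked example

```r
library(lfpbarcode)
sim <- simulateCohort(cohortSpec(n_per_group = 2, duration_s = 60, seed = 42))
rec <- sim$subjects[["control_01"]]$recording
rec
#> Recording 'control_01' (control): 3 region(s) x 60000 samples @ 1000 Hz (60.0 s), 4 unit(s)
#>   regions: OB, aPC, LEC

bandPowerDb(lfpSignal(rec, "OB"), samplingRate(rec), "gamma")
#> gamma (36-95 Hz): 22.04 dB re 1 uV^2

bandCoherence(lfpSignal(rec, "OB"), lfpSignal(rec, "aPC"), samplingRate(rec))
#> Coherence (59 segments): theta 0.122, beta 0.185, gamma 0.645

pacMI(bandpassAnalytic(lfpSignal(rec, "OB"), 1000, "theta"),
      bandpassAnalytic(lfpSignal(rec, "aPC"), 1000, "gamma"))
#> PAC (tort): MI = 0.003377, preferred phase -0.02 rad (18 bins)

spikePhaseLocking(spikeUnits(rec)[[1]], lfpSignal(rec, "OB"), 1000, "gamma")
#> Phase locking 'control_01_u01_gamma' to gamma: mrl = 0.683 at -0.03 rad, Rayleigh p = 9.45e-75 (n = 317)

ba <- barcodeAnalysis(rec, pipelineConfig(n_barcodes = 4), seed = 7)
round(barcodeScore(ba$strengths, sim$subjects[["control_01"]]$events, "novel"), 3)
#> barcode_1 barcode_2 barcode_3 barcode_4
#>     0.629     0.609     0.695     0.798

et <- explorationTimes(sim$subjects[["control_01"]]$events, c("novel", "familiar"))
discriminationIndex(et[["novel"]], et[["familiar"]])
#> DI = 0.428 (novel 32.6 s, familiar 13.1 s)
```

Reading the numbers: this control subject carries ~22 dB of OB gamma power
and OB–aPC gamma coherence ≈ 0.65; theta-phase→gamma-amplitude coupling
(MI ≈ 0.0034) is weak but far from the ~1e-5 floor of uncoupled signals;
the first OB unit is strongly gamma-locked (mrl 0.68, Rayleigh p ≈ 1e-74);
barcode 4 aligns best with novelty epochs (ROC score 0.80); and the animal
prefers the novel object (DI = 0.43). A lesion-group subject shows the
opposite pattern on every axis. `runPipeline(out_dir)` chains all stages on
a simulated cohort and writes tidy CSV/JSON plus a checksummed manifest;
`pipelineReport(out_dir)` summarizes a finished run.

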