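Package: lfpbarcode
Title: Cross-Regional Neural Oscillation Analysis with Co-Activation Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multi-region local field potential (LFP) recordings
    from the olfactory network (olfactory bulb, anterior piriform cortex,
    lateral entorhinal cortex): Welch band power and cross-spectral coherence,
    time-lagged cross-correlation, theta-gamma phase-amplitude coupling,
    spike-phase locking with Rayleigh tests, spike-triggered LFP averages, a
    masked empirical-mode-decomposition + ICA "barcode" method that extracts
    recurring cross-regional oscillatory co-activation motifs, linear-SVM
    population decoding with shuffle-calibrated chance intervals, and
    random-forest forecasting of later behavioral outcome from early
    oscillatory features. Includes a synthetic cohort generator with planted
    spectral, coupling, spiking and behavioral ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    e1071,
    randomForest,
    ica,
    rhdf5,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    clue,
    withr
Config/testthat/edition: 3
Collate: 
    'lfpbarcode-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'bands.R'
    'barcode.R'
    'behavior.R'
    'cohort.R'
    'coupling.R'
    'decode.R'
    'emd.R'
    'io.R'
    'pipeline.R'
    'signal-utils.R'
    'simulate.R'
    'spectral.R'
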