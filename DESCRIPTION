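Package: alphaP1
Title: Pre-Target Alpha Oscillations and P1 Evoked Responses in Epoched EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for studying how pre-stimulus
    alpha-band (8-14 Hz) oscillatory power relates to the early visual P1
    evoked response in epoched multichannel EEG. Provides amplitude-threshold
    epoch rejection, spherical-spline channel interpolation and surface
    Laplacian (current scalp density) transformation, zero-phase Butterworth
    filtering, grand-average and single-trial P1 quantification, Morlet-wavelet
    time-frequency decomposition with percent-signal-change baselining,
    cluster-corrected paired permutation tests over time, balanced two-by-two
    repeated-measures contrasts, and Spearman correlations with bootstrap
    confidence intervals and bootstrap correlation-difference tests. A
    synthetic-EEG generator with known injected alpha and P1 condition effects
    makes every stage verifiable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
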