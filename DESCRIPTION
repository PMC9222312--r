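Package: fwaver
Title: F-Wave Extraction from Single-Lead Atrial Fibrillation ECG by
    Resonance-Based Signal Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting atrial fibrillatory (F-) waves from
    single-lead electrocardiograms. Implements an invertible tunable
    Q-factor wavelet transform (TQWT) as an oversampled iterated
    two-channel filter bank, morphological component analysis of an ECG
    trace into oscillatory (F-wave) and transient (QRST) components
    solved with the split augmented Lagrangian shrinkage algorithm
    (SALSA), genetic-algorithm selection of the Q-factor pair by the
    kurtosis difference of the separated components, a parametric
    simulator of AF ECG records built on the sawtooth F-wave model with
    a synthetic ventricular beat generator, time- and frequency-domain
    evaluation metrics (RMSE, NMSE, Welch power spectra, dominant
    frequency, spectral concentration), and average-beat-subtraction and
    beat-stacking PCA reference extractors for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
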