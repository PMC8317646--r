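Package: stresseeg
Title: Individualized EEG-Based Regression of Self-Perceived Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantitative, per-participant stress assessment from
    frontal EEG recorded over a stress-relax session (arithmetic psychosocial
    stressor followed by virtual-reality relaxation). Provides a
    protocol-faithful synthetic session generator, the preprocessing chain
    (notch and zero-phase Butterworth bandpass filtering, resampling to nominal
    phase length, 2-s epoching, amplitude-based artifact zeroing, per-epoch
    detrending and standardization), extraction of seven spectral features
    (band powers in Delta through Gamma, relative gamma, frontal alpha
    asymmetry) with moving-average smoothing, interpolation of sparse 1-5
    self-perceived stress surveys onto the epoch timeline, grid-search
    cross-validated fitting of ridge, random forest, multi-layer perceptron and
    support vector regressors, and evaluation via the mean squared percentage
    error and squared Pearson correlation with cohort-level aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    ranger,
    e1071,
    zoo,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
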