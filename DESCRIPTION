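Package: pixelMSI
Title: Single-Pixel Classification of MALDI Mass Spectrometry Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of MALDI-TOF mass spectrometry imaging
    (MSI) data for multi-class tissue classification from individual
    spectra (the single-pixel approach). Implements spectral
    preprocessing (mass-channel unification, baseline subtraction,
    medcouple-based TIC outlier flagging, FFT alignment, TIC
    normalization), Gaussian-mixture modeling of the average spectrum
    with component pruning and merging, per-pixel component abundance
    estimation by convolution, intensity-class stratification of
    components, normalized dot-product spectrum similarity with
    intra-/inter-class cumulative distributions, an ensemble of
    one-vs-one linear SVM classifiers with univocal pixel voting and
    core-level majority aggregation under patient-stratified
    cross-validation, Cohen's d effect-size screening of discriminatory
    components, and mass-tolerance peptide annotation. A synthetic-data
    generator with ground truth supports parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    mclust,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
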