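Package: needlespec
Title: Tissue Classification from Diffuse Optical Needle-Probe Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pipeline for real-time tissue classification from diffuse
    optical spectroscopy recorded through a fiber-enhanced core biopsy
    needle. Covers white-standard/dark calibration, moving-average
    smoothing, min-max normalization and band restriction of raw
    spectrometer counts; four feature-extraction schemes (full-range,
    selected bands, point features, slope features); linear-SVM and KNN
    multiclass classifiers with score-averaged combinations, stratified
    k-fold cross-validation and subject-independent holdout; per-class
    confusion-matrix statistics; and a simulated fixed-rate streaming
    classifier with class-boundary exclusion. A seeded synthetic spectra
    generator emulates the multi-subject, eight-class structure of
    needle-probe recordings so the whole pipeline is testable without
    instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
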