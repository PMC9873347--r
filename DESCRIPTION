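Package: ehgtools
Title: Electrohysterogram Feature Extraction and Preterm-Birth Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for classifying preterm versus term
    pregnancies from multichannel electrohysterogram (EHG) recordings.
    Provides WFDB input/output, z-score normalization, zero-phase IIR
    subband filtering (0.3-1, 1-2 and 2-3 Hz), overlapping 120-second
    windowing, a 33-feature set per window (linear, entropy-based and
    wavelet time-frequency descriptors), a four-algorithm feature
    selection combination rule, SVM-family classifiers evaluated with
    k-fold cross-validation against a record-independent test set, and
    per-feature Mann-Whitney screening. A synthetic EHG cohort generator
    with contraction bursts, 1/f baseline noise and maternal-ECG-like
    interference makes every stage testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    e1071,
    MASS,
    rpart,
    stats,
    graphics,
    utils,
    tibble,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
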