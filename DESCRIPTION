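Package: ehds
Title: Hypertension Detection from Pulse Plethysmograph Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classification pipeline for single-channel pulse plethysmograph
    (PuPG) recordings that separates normotensive from hypertensive signals.
    Provides empirical mode decomposition (EMD) and discrete wavelet transform
    (DWT) denoising with energy- and frequency-based component rejection, a
    fixed registry of 102 multi-domain signal features (time, spectral,
    cepstral, chroma, sEMG-style, moment, Hjorth, fractal-chaos and local
    ternary pattern families), hybrid feature selection and reduction (seven
    ranking methods fused by mean rank followed by kernel PCA), a weighted
    k-nearest-neighbour classifier with a roster of comparison baselines,
    stratified cross-validation with pooled confusion-matrix reporting, and a
    seeded synthetic two-class PuPG generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    MASS,
    rpart,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
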