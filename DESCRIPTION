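Package: afdetect
Title: Multimodal Atrial Fibrillation Detection from 12-Lead ECG with HRV and Demographic Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for detecting atrial
    fibrillation and atrial flutter from short 12-lead ECG recordings.
    Provides a synthetic ECG cohort generator (irregular RR intervals and
    absent P-waves for the AF class, class-correlated demographics),
    wavelet denoising and Pan-Tompkins-style R-peak detection,
    heart-rate-variability feature extraction (SDNN, SDSD, RMSSD, pNN20,
    pNN50, HR MAD), compact 1-D convolutional network backbones with a
    two-stream multimodal fusion head, gradient-boosted-tree stacking on
    network embeddings, imbalance-aware training with class weighting and
    plateau learning-rate scheduling, bootstrap confidence intervals for
    all confusion-derived metrics and AUROC, and gradient saliency maps
    for signal-level interpretation. Includes a minimal WFDB format-16
    reader and writer for interoperability with PhysioNet-style archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
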