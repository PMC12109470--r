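Package: eegstack
Title: Region-Wise EEG Feature Extraction and Stacking-Ensemble Detection of Depression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for resting-state EEG analysis of major depressive
    disorder: synthetic two-group cohort generation, preprocessing (average
    reference, zero-phase FIR band-pass and notch filtering, ICA-based blink
    suppression), overlapping-epoch segmentation with amplitude quality control,
    a 95-column region-wise feature schema combining spectral (Welch PSD with
    Simpson band integration), temporal, nonlinear (sample entropy, Higuchi
    fractal dimension, Hurst exponent, Shannon entropy, C0 complexity) and
    time-frequency features, significance-routed feature selection
    (Shapiro-Wilk / Levene gating into ANOVA or Mann-Whitney, Bonferroni
    adjusted), a stacking ensemble classifier with feature passthrough, and
    brain-region ablation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    rpart,
    randomForest,
    xgboost,
    nnet,
    car,
    jsonlite,
    withr,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'eegstack-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'temporal.R'
    'nonlinear.R'
    'regions-bands.R'
    'psd.R'
    'features.R'
    'selection.R'
    'metrics.R'
    'learners.R'
    'stacking.R'
    'crossval.R'
    'ablation.R'
    'bandreport.R'
    'channels.R'
    'io-edf.R'
    'io.R'
    'segment.R'
    'preprocess.R'
    'synthetic.R'
    'pipeline.R'
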