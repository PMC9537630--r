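Package: PWaveAF
Title: P-Wave Morphology Features from Long-Term Single-Lead ECG for
    Postoperative Atrial Fibrillation Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates long-term single-lead electrocardiograms with known
    per-beat P-wave ground truth together with a matched two-group surgical
    cohort, conditions the signal (zero-phase Butterworth band-pass and
    moving-average smoothing), detects QRS complexes and delineates P waves
    at their isoelectric-line intersections, computes seven per-patient
    P-wave parameters (Pmax, Pmin, Pmean, Pstd, P-wave dispersion, Pptmean,
    Pptstd), reproduces the cohort group-comparison statistics (pooled t,
    Mann-Whitney, chi-square, Fisher), and fits clinical and clinical+ECG
    logistic models with ROC/AUC as well as an RBF support-vector-machine
    classifier tuned by stratified fivefold cross-validated grid search
    under class-balanced training splits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    signal,
    e1071,
    pROC,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'reference-tables.R'
    'simulate-ecg.R'
    'simulate-cohort.R'
    'preprocess.R'
    'qrs.R'
    'delineate.R'
    'pfeatures.R'
    'cohort-stats.R'
    'roc.R'
    'splits.R'
    'svm.R'
    'logistic.R'
    'io.R'
    'pipeline.R'
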