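Package: nirscassava
Title: Portable NIRS Phenotyping Pipeline for Cassava Root Quality Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, chemometric calibration and selection-concordance
    analysis for handheld near-infrared spectroscopy (NIRS) phenotyping of
    cassava root quality traits (starch content and dry matter content).
    Provides a synthetic-data generator for SCiO-like 740-1070 nm spectra
    tied to plot-level traits under a multi-environment variance-component
    model; spectral pre-treatments (SNV, MSC, Savitzky-Golay, gap-segment
    derivative, detrend) and IQR outlier screening; repeated cross-validated
    calibration with PLS (NIPALS), RBF support vector regression and
    gradient boosting; chemometric validation metrics (R, R2, RMSE, bias,
    RPD, RPIQ); REML variance components with BLUP deregression; and
    Cohen's kappa concordance between phenotype-based and model-based
    selection of top clones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    signal,
    e1071,
    xgboost,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
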