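Package: synmark
Title: Brain-Based Biomarker Construction and Validation for Synesthesia
    Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and validates parcellation-based neuroimaging biomarkers
    that separate synesthetes from controls: thirteen feature sets derived
    from cortical surface area, thickness, intracortical myelin, subcortical
    volumes and resting-state functional connectomes (partial correlations,
    degree centrality, connectivity gradients); empirical-Bayes batch
    harmonization (ComBat); staged and single-step cross-validated
    random-forest classification with down-sampling, vote shares and
    permutation-null calibration; and the accompanying mass-univariate and
    effect-size statistics (pooled-variance t maps with FDR control,
    AUC/Cohen's d conversion, bias-corrected Mahalanobis D, noncentral-t
    power analysis). Includes a synthetic-cohort generator emulating the
    statistical structure the analysis assumes, so the full pipeline is
    testable without access-restricted MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
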