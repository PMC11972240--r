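Package: patchleave
Title: Predicting Patch-Leaving Decisions in Visual Foraging from
    Search Organization and Intake Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for stay/leave decisions in visual
    foraging (patch-leaving) tasks. Computes the four classic spatial
    organization indicators of search -- best-r, mean inter-target
    distance, percentage above the optimal (traveling-salesman) path,
    and the intersection rate of the scan path -- incrementally over
    the "trial so far", together with Marginal Value Theorem intake
    rates and their ratio (RIAIR). Builds PCA-loading-weighted and
    unweighted composite organization scores after Horn's parallel
    analysis, evaluates every predictor of the leaving decision with
    ROC curves, Youden-optimal thresholds and DeLong or
    Hanley-McNeil confidence intervals, and combines two predictors
    into a single compound AND/OR leaving criterion via the
    maximum-likelihood ROC combination. Includes an agent-based
    foraging simulator (static and moving displays, parameterized
    collection strategies and quitting rules) that generates event
    logs with known ground truth for validating the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
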