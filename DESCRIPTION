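Package: brainfp
Title: Functional Connectome Fingerprinting and Fingerprint-Informed
    Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for resting-state functional connectome fingerprinting:
    split-half connectome construction, covariate residualization,
    identifiability metrics (I_self, I_others, I_diff, normalized
    differential identifiability, success rate) with bootstrap inference,
    edgewise test-retest reliability via ICC(1,1) with repeated
    subsampling, permutation-based differential reliability maps with
    Benjamini-Hochberg FDR control, weighted graph-topology features on
    fingerprint-masked subnetworks, and nested leave-one-out
    cross-validated classification of treatment response with permutation
    significance testing. Includes a synthetic cohort simulator with
    planted subject-unique connectivity signatures, group-specific edge
    stability differences, covariate effects, and outcome coupling, so the
    whole pipeline can be exercised end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    randomForest,
    xgboost,
    e1071,
    rpart,
    pROC
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
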