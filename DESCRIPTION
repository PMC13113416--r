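Package: emgdose
Title: EMG-Guided Exercise Time Allocation for Shoulder Rehabilitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates multi-channel surface electromyography (sEMG) cohorts
    with planted movement-dependent activation structure, extracts
    sliding-window RMS features with peak normalization, benchmarks
    cross-subject muscle-activation prediction under leave-one-subject-out
    validation (support vector, k-nearest-neighbour, adaptive-boosting and
    gradient-boosted-tree regressors), and converts predicted superficial and
    deep activation profiles into an optimized allocation of a fixed-length
    therapy session across four shoulder exercises via a variance-penalized
    constrained objective. Includes an exhaustive grid oracle for verifying
    the constrained solver and an end-to-end reproducible pipeline.
License: MIT
Encoding: UTF-8
Imports:
    caret,
    e1071,
    jsonlite,
    nloptr,
    rpart,
    signal,
    stats,
    utils,
    xgboost,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
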