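Package: itug
Title: Instrumented Timed Up and Go Analysis with Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the instrumented Timed Up and Go (iTUG)
    test recorded with a trunk-worn smartphone inertial sensor. Reads raw
    accelerometer and gyroscope logs, segments repeated TUG trials into
    Sit-to-Walk, walking, turning and Turn-to-Sit phases, computes a
    catalogue of 78 temporal, intensity and smoothness features, and
    predicts Community Balance and Mobility Scale (CBMS) scores with a
    partial least squares regression (PLS1) validated by Monte-Carlo
    cross-validation with embedded feature screening, variable importance
    in projection (VIP) scoring and paired between-model comparison of
    prediction error. Includes a calibrated synthetic cohort and signal
    generator so the full pipeline can be exercised and tested without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
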