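Package: igwave
Title: Autoantibody Array Signatures of Aging: Trajectories, Waves, and
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for serum IgG autoantibody protein-array
    profiles across age and neurodegenerative disease cohorts. Implements
    normexp background correction, between-array quantile normalization and
    log10 transformation; per-feature covariate-adjusted linear models with
    type-II sums of squares, per-term F tests, Benjamini-Hochberg adjustment
    and partial eta squared; LOESS trajectory smoothing with complete-linkage
    hierarchical clustering; sliding-window differential expression (DE-SWAN)
    with wave detection and overlap reporting; Fisher's exact
    over-representation tests against the array background; and resampled
    penalized-logistic classification (elastic-net importance index, top-k
    ridge refits). A synthetic-cohort generator with known ground truth
    (age, sex and disease effects, step waves, trajectory templates,
    background and array-scale artifacts) makes every stage testable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    limma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
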