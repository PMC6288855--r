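Package: survscreen
Title: Survival-Marker Gene Screening in Multi-Batch Transcriptomic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery pipeline for prognostic (survival-marker) genes in
    colorectal cancer from merged multi-batch expression cohorts: batch
    integration with regression and mixing diagnostics, stage-contrast
    moderated differential expression, per-gene minimum-p-value cutpoint
    Kaplan-Meier screening with Cox hazard ratios, resampling stability
    ranking, and an L1-penalized multivariate Cox risk score with a
    cross-validated risk threshold. Includes a synthetic multi-batch
    cohort generator with known ground truth so every stage has an
    offline recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    glmnet,
    limma,
    cluster,
    stats,
    utils
Suggests:
    sva,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
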