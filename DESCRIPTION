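Package: phenodii
Title: Dietary Inflammation and Phenotypic Age in Complex Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes phenotypic age (PhenoAge) from chronological age and
    nine routine clinical biomarkers via a Gompertz mortality model, scores
    the dietary inflammatory index (DII) from 26 daily nutrient intakes, and
    relates the two with design-based weighted linear regression for
    stratified, clustered survey samples (Taylor-linearized variance, Wald
    tests for effect modification). Includes the full analysis pipeline for
    NHANES-style cohorts (exclusion cascade, covariate recoding, weighted
    descriptive tables, adjusted models, stratified forest analysis) and a
    synthetic cohort generator with exactly known ground truth, so every
    stage is testable without survey downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, sandwich
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
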