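Package: maritalens
Title: Weak-Supervision Ensembles for Marital Status Phenotyping from Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for extracting marital status from the social-history sections of
    clinical notes by aggregating weak label sources (a structured demographics field
    and two text extractors) with four ensemble rules (unanimous vote, majority vote,
    per-class precision selection, and a random-forest meta-classifier), for
    bootstrapping a bag-of-ngrams student classifier from ensemble pseudo-labels to
    raise recall, and for downstream cohort analysis of marital-status change:
    eligibility filtering of admission timelines, change classification, age-matched
    downsampling, condition prevalence and new-diagnosis/recovery rates with exact
    (Clopper-Pearson) binomial confidence intervals, rank-sum comparisons with Holm
    adjustment, and multiclass precision/recall/F1 evaluation with macro and weighted
    averaging. Includes synthetic note-corpus and longitudinal-cohort generators so
    the full pipeline is testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
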