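Package: cohortscores
Title: Catalog-Driven Summary Scores for Cohort-Study Tabulated Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A declarative engine for computing assessment summary scores
    (means, sums, prorated sums, counts, normative t-scores, and their
    number-missing companions) from rectangular cohort-study data. Score
    definitions live in a validated catalog that names each score with a
    hierarchical domain/respondent/table/scale grammar and declares its
    items, scoring kernel, and missing-item tolerance. Includes generic
    row-wise scoring kernels with an explicit missingness contract,
    column-level transforms for survey data curation (recoding, level
    collapsing, column coalescing, and making longitudinal variables
    static), tabular and catalog readers/writers, a command-line
    interface, and seeded synthetic-data generators so every behavior is
    testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
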