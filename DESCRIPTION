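Package: famrisk
Title: Family-History Assessment and Risk Stratification for Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for collecting and analysing family history of colorectal
    cancer (CRC). Provides a pedigree data model with three-side grouping and
    first-/second-degree relative classification, a configurable guideline rule
    engine that maps a pedigree to one of four lifetime-risk categories with
    surveillance recommendations, two equivalent intake modes (a sequential
    one-question-per-page questionnaire flow and a single-form diagram intake),
    the statistical pipeline used to evaluate such interfaces (negative-item
    recoding, Little's MCAR test with EM estimation, deterministic single
    imputation, Cronbach's alpha, pooled t-test with a Shapiro-Wilk normality
    gate and a tie-corrected Mann-Whitney fallback), and seeded synthetic
    generators for pedigrees and usability-study datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
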