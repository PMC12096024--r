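Package: eduscore
Title: Blinded Evaluation of Personalized Patient-Education Content
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for blinded, paired evaluation of
    personalized patient-education materials (for example, knee-osteoarthritis
    self-management guidance written by clinicians versus a language model).
    Implements authoring efficiency in words per minute, four grade-level
    readability indices (Flesch-Kincaid, Gunning Fog, Coleman-Liau, SMOG) on a
    deterministic tokenizer, a weighted guideline-consensus accuracy score over
    treatment mentions, 100-point rubric instruments (personalization,
    comprehensiveness, safety) with dual-rater adjudication and third-rater
    median resolution, and paired arm comparisons with normality-driven
    selection between the paired t test and an enumeration-exact Wilcoxon
    signed-rank test. A synthetic-cohort generator with ledgered token
    statistics and noisy simulated raters supports calibration and power
    studies without access to clinical texts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
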