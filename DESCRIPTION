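Package: regexmart
Title: Rule-Based Extraction of Pulmonary Function Test Reports into a
    Research Data Mart
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parses machine-generated pulmonary function test (PFT) text
    reports into a typed, analyzable data-mart table using a declarative
    ruleset of regular expressions with named capture groups. Ships a
    canonical 107-field PFT dictionary with a 39-rule default ruleset, a
    seeded synthetic cohort and report generator with ground truth and an
    injectable transcription-error plan, a batch mart builder with
    quarantine handling and CSV export, and a validation workflow that
    selects each subject's index test and measures cell-level congruence
    between automated extraction and simulated manual chart abstraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
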