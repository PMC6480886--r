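Package: chronicagree
Title: Validating Patient-Reported Chronic Diseases Against Hospital
    Administrative Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the agreement between chronic diseases
    reported by patients on pre-operative questionnaires and diagnoses
    derived from linked hospital administrative records. Implements cohort
    construction with deduplication and exclusion accounting, ICD-10
    condition code maps with two-stage backward-coding augmentation,
    look-back window derivation of administrative disease flags, and
    agreement statistics (sensitivity, specificity and Cohen's kappa with
    large-sample confidence intervals), together with a synthetic
    linked-record generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
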