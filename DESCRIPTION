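Package: occumine
Title: Text Mining Occupations from Psychiatric Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting who-does-what from the free text of mental
    health records. Locates personal-history sections, detects occupation
    mentions with a hybrid gazetteer and conditional-random-field tagger,
    classifies the occupation relation (patient, family member, clinician,
    other person) with a support-vector machine backed by cue rules, and
    applies a healthcare-occupation filter so that clinician job titles are
    never attributed to the patient. Includes a seeded synthetic note
    generator with exact gold-standard annotations, strict span-and-relation
    evaluation with Cohen's kappa agreement, and patient-level occupation
    profiling with logistic-regression models of occupation recording.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
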