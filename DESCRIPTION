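Package: habsi
Title: Automated Surveillance and Classification of Health Care-Associated
    Bloodstream Infections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based surveillance engine for health care-associated
    bloodstream infection (HABSI) built on flat-table electronic medical
    record extracts. Links re-admissions into hospitalization episodes,
    screens blood cultures and vital signs to detect HABSI candidates
    (48-hour hospital-acquired rule, strict fever criterion,
    common-commensal corroboration, clinical sepsis pathway), deduplicates
    polymicrobial and persistent bloodstream infections, and classifies
    events as primary (catheter-related, central line-associated, or
    other), secondary, or clinical sepsis. Ships a seeded synthetic cohort
    generator with ground-truth labels, patient-level evaluation
    (sensitivity, specificity, predictive values, Cohen's kappa with
    confidence intervals), incidence and confirmation-delay statistics,
    monthly surveillance reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
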