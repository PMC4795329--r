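Package: pcmcat
Title: Partial Credit Model Computerized Adaptive Testing for Patient
    Experience Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Rasch partial-credit-model (PCM) engine for computerized
    adaptive testing (CAT) of polytomous patient-reported experience
    questionnaires.  Provides an item-bank data model with conditional-path
    (skip item) routing, PCM category probabilities and score moments,
    simulation of synthetic respondent cohorts, maximum-likelihood person
    estimation with standard errors and person/item fit statistics
    (infit/outfit mean squares), maximum-information adaptive item selection
    with reliability- and convergence-based stopping rules, expected-response
    imputation of unanswered items, and a scenario study comparing adaptive
    testing against full-length and random short-form administration.
    Ships a 24-item inpatient-experience item bank calibrated in logits.
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
    optparse
Config/testthat/edition: 3
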