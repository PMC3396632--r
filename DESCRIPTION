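Package: conflictmh
Title: Post-Conflict Mental Health Burden and Service Needs Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects the post-conflict burden of severe PTSD and major
    depression and the mental health services needed to respond to it.
    Implements random-effects meta-regression of logit-transformed survey
    prevalences with study-level covariates (political terror, traumatic-event
    exposure, time since conflict), REML and moment (extended
    DerSimonian-Laird) estimation, stratified prevalence prediction with
    back-transformed confidence intervals, severity categorisation and
    random-effects pooling of severe-case proportions, comorbidity splitting,
    population case projection with explicit rounding conventions, and an
    mhGAP-style service-coverage and full-time-equivalent staffing model with
    workforce-gap analysis.  A synthetic study-table generator emulating the
    assumed data-generating process supports parameter-recovery and coverage
    experiments end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
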