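Package: mwtrans
Title: Multistate Markov Models for Metabolism-Weight Phenotype Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying transitions among the six metabolism-weight
    phenotypes (metabolically healthy/unhealthy crossed with normal weight,
    overweight and obesity) in longitudinal health check-up panels.
    Classifies raw check-up measurements into phenotypes using Chinese BMI
    cut-offs and revised NCEP ATP III metabolic criteria, applies cohort
    eligibility rules, tabulates observed transitions, and fits a
    continuous-time six-state Markov model to panel-observed (interval
    censored) state sequences by maximum likelihood, with proportional
    intensity covariate effects, mean sojourn times, multi-year transition
    probability predictions, and observed-versus-expected prevalence
    goodness-of-fit checks. Includes an exact (event-driven) cohort
    simulator that generates both latent state paths and measurement-level
    check-up records consistent with the phenotype definitions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), Matrix, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
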