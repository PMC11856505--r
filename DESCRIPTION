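Package: kidlb
Title: Live-Birth Prediction from Day 2 Embryo Morphokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Penalized additive logistic modelling of live birth after Day 2
    embryo transfer from time-lapse morphokinetic annotations (t2, second
    cell cycle duration, multinucleation) with optional maternal age, cycle
    level random intercepts and REML smoothing selection. Includes clustered
    bootstrap cross-validated AUC, age-by-score tertile stratification with a
    counterfactual age-averaging evaluation, ICSI t2 timing sensitivity
    curves, and a seeded synthetic cohort generator so the full analysis is
    reproducible without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    digest
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
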