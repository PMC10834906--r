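Package: roadlpe
Title: Prevalence Effects in Road-Hazard Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for studying the low prevalence effect (LPE)
    in road-hazard detection as a function of perceived hazardousness.
    Merges trial-level hazard-detection responses with continuous
    hazardousness ratings, fits binomial psychometric and mixed-effects
    models, extracts 50% detection thresholds and threshold-shift LPEs,
    computes quartile-wise miss-rate LPE statistics, and runs
    within-participant permutation tests with Bonferroni control. Includes
    a signal-detection synthetic-observer generator that emulates the
    multi-experiment prevalence-manipulation design, so the whole pipeline
    is exercisable with known ground truth and no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
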