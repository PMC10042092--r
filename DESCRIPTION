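Package: textquit
Title: Personalized Text-Message Smoking-Cessation Intervention Engine and
    Trial Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, running and evaluating a theory-based
    personalized text-message smoking-cessation programme. Implements
    protection motivation theory (PMT) scale scoring with weakest-construct
    targeting, a transtheoretical-model stage state machine, a three-layer
    message bank with validation and fixture generation, a 90-day
    per-participant delivery schedule, stratified trial randomization,
    two-proportion sample-size planning, Russell-standard abstinence
    adjudication, 2x2 effect estimation, and a synthetic smoker cohort
    simulator so a complete randomized trial can be run end to end without
    real participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
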