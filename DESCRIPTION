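Package: rehabElo
Title: Elo-Family Rating Systems for Web-Based Cognitive Rehabilitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rates patients and rehabilitation tasks as players in a
    paired-comparison system. Each execution of a web-based cognitive
    rehabilitation task is treated as a match between the patient and the
    task, scored from the 0-100 compliance result, and fed to one of four
    rating engines (Elo, Glicko, Glicko-2, Stephenson) with batch
    rating-period semantics. Early ratings stratify patients into
    low/mid/high terciles; a forward-stepwise regression harness with
    multicollinearity, autocorrelation and discrimination diagnostics
    relates ratings to memory outcomes; and a seeded synthetic-cohort
    generator reproduces the statistical structure of a stroke
    rehabilitation cohort so the whole pipeline runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    lmtest,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
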