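Package: gazehand
Title: Eye-Hand Coordination Analysis for Pegboard Dexterity Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-rate behavioral recordings (force,
    hand, and gaze position) from sequential peg placement and retrieval
    tasks. Segments force signals into collection, transport, delivery, and
    peg-free actions with PELT change-point detection, detrends the
    accumulating peg-weight load, computes the gaze-index separation index
    (GISI) at action-progress quartiles and at peak normal force, estimates
    gaze-hand temporal offsets by cross-correlation, and fits linear
    mixed-effect models with Type-2 Wald tests, Tukey-adjusted post hoc
    contrasts (delta and delta-delta), and learning-trend slopes. Includes a
    pegboard-task simulator with injectable condition effects so every stage
    is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    withr,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
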