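Package: canipbpk
Title: Whole-Body Physiologically Based Pharmacokinetics of Propofol in Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-body, flow-limited physiologically based pharmacokinetic
    (PBPK) model of intravenous propofol in dogs, with tools for clearance
    calibration against literature exposure data, virtual canine populations
    with graded hepatic impairment, geometric-mean-fold-error model validation,
    therapeutic-window compliance, anesthesia-recovery-time estimation, and
    exposure-matched infusion-rate adjustment for impaired animals. All
    simulation results are returned as tidy tibbles and pipe naturally into
    dplyr and ggplot2 workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    deSolve,
    tidyr,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
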