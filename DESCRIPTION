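Package: ccwindows
Title: Exposure Misclassification Assessment for Case-Crossover Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing exposure misclassification induced by the
    choice of control window in pharmacoepidemiological case-crossover
    studies of dispensed medicines. Classifies each subject's exposure
    status (intermittent user, recent stopper, continuous user, non-user)
    under alternative control windows, stratifies subjects by how their
    status changes between windows, applies a deterministic rule engine
    that issues per-stratum correct-/mis-classification verdicts from the
    positions of dispensings relative to window boundaries, estimates the
    discordant-pair odds ratio with a Wald confidence interval for each
    control window, and draws the stratified per-subject dispensing
    timeline that makes the misclassification visible. A seeded synthetic
    claims generator with known archetype structure supports testing and
    demonstration without access to restricted administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
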