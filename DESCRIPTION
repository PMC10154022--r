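Package: crcdisrupt
Title: Microsimulation of Colorectal Cancer Screening Disruptions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative microsimulation of pandemic-induced disruptions to
    colorectal cancer screening. Simulates adenoma-carcinoma natural
    histories in continuous age with counter-based per-person random
    substreams, colonoscopy and fecal immunochemical test (FIT) screening
    with per-size-class test sensitivities, the Multi-Society Task Force
    colonoscopic surveillance state machine, and a grid of cohort by
    disruption scenarios (short-term delays, long-term delays, regimen
    switching, discontinuation). Outcomes are life-years lost to
    disruptions relative to common-random-number counterfactuals, reported
    per 1000 persons with Monte-Carlo standard errors and as ranges across
    two bundled natural-history parameterizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
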