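Package: hrrflux
Title: High-Resolution Respirometry Flux Analysis for SUIT Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns oxygraph chamber oxygen traces and substrate-uncoupler-
    inhibitor titration (SUIT) event logs into state-resolved, background- and
    ROX-corrected oxygen fluxes, and derives the ratio panel used in
    mitochondrial bioenergetics: flux control ratios, ATP-coupled (net) flux,
    coupling efficiencies, respiratory reserve, complex II-linked capacity and
    substrate control factors, with group-level summaries and t-test
    comparisons. Includes a seeded chamber simulator (piecewise-steady
    respiration with exponential transitions, linear-in-oxygen instrumental
    background, Gaussian sensor noise) so the whole pipeline is testable
    against known ground truth, plus control and MPP+-treated presets whose
    ratio structure mirrors published neuroblastoma measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
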