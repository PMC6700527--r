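Package: grmetrology
Title: Growth-Rate Inhibition Metrics and Replicate Metrology for
    Plate-Based Drug-Response Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying and stress-testing the reproducibility
    of plate-based drug dose-response assays. Computes growth-rate
    inhibition (GR) values from endpoint cell counts and instantaneous GR
    from live-cell time courses, fits sigmoidal GR curves with a flat-model
    fallback to derive GR50, GRmax, GEC50, GR_inf, Hill slope and GR_AOC,
    decomposes measurement error into technical and biological standard
    errors using the nested well/plate/day replicate combinatorics,
    detects microtiter-plate edge effects, compares direct-count and
    surrogate (ATP-proxy) readouts, and ships a synthetic plate-data
    generator that emulates the replicate structure, noise hierarchy,
    edge fields, surrogate bias and time-varying drug efficacy of a
    multi-center drug-response study, so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
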