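Package: fusefid
Title: Fusion Fidelity Metrics for Epithelial Sheet Closure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative morphodynamics of epithelial fusion during
    Drosophila dorsal closure, starting from tracked live-imaging
    measurements. Provides normalized disparity descriptors between
    contralateral fusing flanks (arc length, fusing-front width, leading-edge
    cell number), equalization-time detection, interface-geometry
    classification (angular/straight/curved) with tricellular interlocking
    calls, cell-rearrangement typing around cell-addition events, a seeded
    synthetic-data generator that emulates the tracked tables with ground
    truth for every classifier, and a reporting pipeline with rank-sum and
    variance-ratio group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
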