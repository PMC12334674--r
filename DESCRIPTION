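Package: noradscope
Title: Quantification Pipelines for Noradrenergic Axon Degeneration Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tested quantification pipelines for studies of locus coeruleus
    axon degeneration in the olfactory bulb: odour-evoked fluorescent
    neuromodulator-sensor movies (z-projection, optional rigid motion
    correction, baseline-window dF/F, 6x6 ROI tiling, response-window
    classification, fraction and grand-average summaries), histological
    fibre/microglia/plaque area-fraction densities with per-layer and
    per-animal summaries and relative-loss contrasts, threshold-based 3-D
    colocalization and engulfment volumetry, two-camera nose-trajectory
    fusion with odour-investigation-zone metrics and buried-food latency
    contrasts, and phagocytic-index normalisation of live-cell uptake time
    courses. Every pipeline stage is paired with a seed-deterministic
    synthetic-data generator with known ground truth, so parameter recovery
    is verifiable without any raw microscopy or behaviour data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    readr,
    withr
Config/testthat/edition: 3
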