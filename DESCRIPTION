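Package: caosc
Title: Single-Cell Calcium Oscillation Quantification for Volumetric Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intracellular calcium oscillations of individual cells
    in two-channel volumetric (4D) fluorescence time-lapse recordings, as used
    to monitor endothelial GCaMP signals during zebrafish sprouting
    angiogenesis. Provides nucleus detection and tracking in the nuclear
    channel, spherical region-of-interest trace extraction from the indicator
    channel, sliding-window baseline estimation and delta-F-over-F0
    normalisation, cohort-calibrated oscillation detection, per-cell frequency
    and amplitude metrics, tip-stalk synchrony classification, spatial
    summaries relative to somite boundaries, and group comparisons. A
    synthetic-data module generates ground-truth scenes and rendered movies so
    every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
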