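Package: flimspine
Title: FLIM-FRET Binding Fractions and Dendritic Spine Plasticity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-spine structural plasticity
    experiments: two-photon fluorescence lifetime (FLIM/TCSPC) decay
    modelling with Gaussian pulse-response convolution and Poisson
    maximum-likelihood fitting, FRET binding-fraction estimation for a
    TrkB activation sensor, dF/F0 spine-volume time courses with
    phase-window statistics, uncaging-locked sweep analysis of
    pH-sensitive reporter release, release-event statistics for TIRF
    recordings, and a synthetic-data generator with ground-truth
    manifests so every stage is testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
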