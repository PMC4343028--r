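Package: cometcal
Title: DNA-Content Gating, Reference-Cell Calibration and Dose-Response
    Analysis for the Comet Assay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzes single-cell gel electrophoresis (comet assay) scoring
    tables in which each comet carries a total fluorescence intensity (TFI)
    proportional to its DNA content. Classifies comets into ploidy or
    genome-size classes by TFI (fixed thresholds, Gaussian-mixture or
    kernel-density valley gating), summarizes DNA damage per class, detects
    and exploits internal fish-erythrocyte reference cells to normalize
    intensities between experiments, and builds and inverts linear radiation
    dose-response calibrations with dynamic-range truncation. Ships a
    synthetic-data generator emulating trimodal testicular cell suspensions
    and 1:1 fish/human cell mixtures across an X-ray dose series, and a
    minimal comet-image simulator verifying that integrated staining signal
    tracks DNA content.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
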