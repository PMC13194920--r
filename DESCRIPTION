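Package: rodmorph
Title: Cell Size Morphometry for Rod-Shaped Bacteria from Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts per-cell length, width, surface area and volume from
    instance-label masks of rod-shaped bacteria using distance-transform and
    medial-skeleton geometry under a spherocylinder model with hemispherical
    caps. Corrects systematic segmentation size bias with a Bayesian linear
    measurement transformation, benchmarks instance segmentations with
    F1-versus-IoU curves, and ships a synthetic fluorescent-membrane
    spherocylinder simulator that provides exact ground truth for testing the
    whole pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    rjags,
    coda,
    car,
    tiff,
    png,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    mgcv
Config/testthat/edition: 3
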