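Package: canopycover
Title: Plot Detection and Green Canopy Cover Extraction from Nadir Field Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting green canopy cover (CC) from nadir RGB
    images of row-sown field trial plots. Implements color-ratio green-pixel
    segmentation, crop-row detection by 1-D kernel-density clustering of the
    vertical pixel distribution, robust row-line fitting and rotation
    alignment, plot-boundary derivation and temporal propagation for closed
    canopies, and merging of row-based and total-fraction CC records. A
    statistical layer provides spatially adjusted genotype means (BLUEs),
    residual-based outlier removal, broad-sense heritability per date,
    penalized-spline (GAM) growth curves with 50%-CC closure and senescence
    timing, height percentiles and trait correlations. A synthetic field
    renderer and trial/weather simulators with exact ground truth make the
    whole pipeline testable without an image archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    lme4,
    MASS,
    png,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
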