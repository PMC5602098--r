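Package: rescover
Title: Crop Residue Cover Measurement Methods: Synthetic Experiment and
    Method Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how alternative measurements of crop residue
    cover compare against a line-transect benchmark. Provides a
    Gaussian-copula generator of plot- and household-level survey records
    with calibrated rank dependence and marginal summaries; procedural
    generators of straw-on-soil RGB field images with exact ground-truth
    masks and of two-band shortwave-infrared rasters; the excess-green
    (2G-R-B) image segmentation chain with Otsu binarisation; a simulated
    line-transect protocol; the Normalized Difference Tillage Index (NDTI)
    with per-plot raster extraction; and a method-comparison framework
    covering Spearman correlation matrices, 30%-threshold confusion,
    AQUASTAT cover categories, and linear probability models of
    measurement error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
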