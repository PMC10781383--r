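Package: leafpigmentr
Title: Leaf Pigment Estimation from Proximal Multispectral Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for estimating total chlorophyll (Chl a+b) and
    carotenoid content of broadleaf samples from six-band proximal
    multispectral images. Covers reference-panel radiometric calibration,
    near-infrared threshold segmentation and leaf labelling, multiplicative
    scatter correction (MSC) of leaf spectra, a registry of 26 vegetation
    indices that together with the 6 bands form a 32-variable
    pseudo-hyper-spectrum, three variable-selection algorithms (correlation
    forward filtering, sequential forward selection, recursive feature
    elimination) wrapped around partial least squares, linear-model and
    RBF support-vector learners, leave-one-out cross-validated PLSR and SVR
    prediction models, and pixel-wise pigment mapping with per-layer
    summaries. A seeded synthetic leaf-scene generator reproduces the
    statistical structure of a field campaign so the full pipeline can be
    exercised and tested without camera data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    mixOmics,
    igraph,
    tiff,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
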