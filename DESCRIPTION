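Package: rdindex
Title: RNA Distribution Indexes from Multichannel Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Alex", "Doran", email = "adoran.dev@example.com",
           role = c("aut", "cre"))
Description: Quantifies how RNA molecules detected by fluorescence in situ
    hybridization are distributed within single cells. Reads multichannel
    TIFF microscopy images, segments the cell (Sobel edge detection,
    dilation, flood fill) and nucleus (Wiener denoising, Otsu threshold),
    supports scriptable polygon-based mask editing, and computes three
    intensity-weighted spatial second-moment statistics per RNA channel:
    the polarization index (PI), the dispersion index (DI) and the
    peripheral distribution index (PDI), together with mean RNA intensity
    and cell area. Includes a fully parameterised synthetic-image
    generator with closed-form ground truth, a threshold-sweep utility
    for background calibration, and a batch command-line pipeline with
    replayable mask edits and CSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
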