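Package: lscitrack
Title: ROI Tracking and Perfusion Quantification for Laser Speckle
    Contrast Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic analysis of laser speckle contrast imaging
    (LSCI) recordings of the foot. Converts speckle contrast to perfusion
    with a two-point instrument calibration, tracks ellipse regions of
    interest across a recording by Canny edge detection and iterative
    closest point (ICP) rigid registration (with a reset at the Buerger's
    test repositioning), segments recordings into timespans of interest
    including detection of the post-occlusive reactive hyperemia peak,
    and validates agreement between tracking approaches with two-way
    random-effects absolute-agreement intraclass correlation
    coefficients. Ships a synthetic speckle phantom generator with known
    ground truth so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    EBImage,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
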