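Package: spharray
Title: Quantitative Image Analysis for Spheroid Microarray Histology
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying immunohistochemistry on spheroid
    microarray sections: hematoxylin/DAB colour deconvolution with
    percent-positive-area and percent-positive-nuclei readouts,
    flat-field illumination correction, watershed nucleus counting,
    bead-based embedding-depth uniformity analysis, robust Z'-factor
    assay-quality statistics, four-parameter logistic dose-response
    fitting, and 6x11 array layout / de-arraying utilities. Includes a
    ground-truthed synthetic image and data generator for validating
    every pipeline, plus a command-line interface for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
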