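Package: lmdpipe
Title: Optically Guided Single-Cell Laser Microdissection Sampling and
    Mass-Spectral Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale implementation of an optically guided single-cell
    sampling and analysis pipeline: bright-field cell recognition on slide
    images, laser toolpath planning for interior raster ablation and
    cut-and-drop microdissection, extraction and fixed-grid binning of
    per-cell time-of-flight mass spectra, and two-component PCA-LDA
    classification of single-cell lipid and pigment profiles.  Ships
    ground-truthed synthetic image, spectrum and run generators so the whole
    pipeline is testable end to end without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    polyclip,
    jsonlite,
    yaml,
    rlang,
    tiff,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mzR,
    optparse,
    MASS,
    mgcv,
    withr,
    knitr
Config/testthat/edition: 3
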