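Package: gliotex
Title: Texture and Color Feature Ensembles for Glioma Grading from
    Histopathology Tiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A computer-aided glioma-grading pipeline for H&E-stained
    histopathology tiles: two-step contrast enhancement (global
    log-normalization followed by contrast-limited adaptive histogram
    equalization), tiling with watershed nuclear-density region-of-interest
    selection, six hand-crafted texture and color feature families
    (co-occurrence and run-length statistics, multi-resolution rotation
    invariant local binary patterns with heterogeneity weighting, a
    multi-scale pyramid LBGLCM descriptor, color moments and histograms, and
    the rotation- and scale-invariant hybrid color-texture descriptor),
    non-negative matrix factorization feature reduction, and a
    majority-voting ensemble of an RBF-kernel support vector machine, a fast
    large-margin linear classifier and a random decision tree, with grouped
    cross-validation and holdout evaluation.  Includes a synthetic
    labeled-texture generator so the whole pipeline is testable without
    whole-slide archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    e1071,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
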