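Package: gliascope
Title: Astrocyte Morphometry, Calcium Event Detection, and Viability
    Quantification from Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable implementation of an image-analysis pipeline
    for astrocyte cultures: 3D reconstruction and segmentation of
    membrane/nucleus confocal stacks with five shape descriptors (aspect
    ratio, circularity, centroid distance, solidity, ramification) and
    quality-control filters; calcium time-lapse processing (segmentation
    masks, ROI trace extraction, background-referenced dF/F0, Butterworth
    band filtering, threshold-and-zero-crossing event detection with
    kinetics); live/dead viability counting from three-channel images; and
    the accompanying statistical battery (one-way ANOVA with Tukey HSD,
    two-sample t, Kolmogorov-Smirnov, iterative Grubbs outlier testing).
    Includes a seeded synthetic-data generator that emits microscopy-like
    inputs with exact ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    igraph,
    tiff,
    yaml,
    jsonlite,
    readr,
    pracma,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
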