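Package: heterophylly
Title: Comparative Transcriptomics and Cell-Shape Morphometrics for
    Heterophylly Candidate-Gene Discovery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale reimplementation of the comparative
    transcriptomics pipeline used to dissect heterophylly (dimorphic
    leaf development) in the amphibious plant Callitriche palustris,
    together with the polygon morphometrics used to quantify leaf cell
    shape. Provides a negative-binomial count simulator with planted
    differential-expression signatures, trimmed-mean (TMM)
    normalization, a conditional exact negative-binomial two-group
    test, the direction-consistent DEG intersection cascade with
    ploidy-aware cross-species ortholog exclusion and transcription
    factor candidate selection, hypergeometric GO-term enrichment with
    Benjamini-Hochberg correction, polygon shape descriptors
    (circularity, solidity, moment-ellipse aspect ratio, minimum
    bounding rectangle) with their statistical layer (Welch's t,
    Hedges' g, Tukey HSD, PCA), and a reproducible file-based pipeline
    with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
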