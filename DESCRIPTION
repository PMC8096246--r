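Package: evaquant
Title: Quantification of Epigenetic Visualization Assay (EVA) Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Image analysis and statistics for the Epigenetic Visualization
    Assay (EVA), a two-channel fluorescence in situ readout of epigenetic
    mark density at individual gene loci. The pipeline registers channels to
    correct chromatic shift, segments nuclei, detects fluorescent foci with a
    Laplacian-of-Gaussian spot detector, computes rim-corrected
    sensor/detector (G/R) intensity ratios per locus, and implements the
    downstream statistical layer: negative-control normalization,
    dynamic-range calibration from labeled-fraction mixing series, per-cell
    allelic classification, rank-sum testing and sample-size estimation. A
    synthetic specimen generator with exact ground truth makes every stage
    verifiable without microscopy data, and a probe-tiling module designs
    the gene-specific 30-mer oligo probes used by the assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
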