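Package: synmapr
Title: Single-Synapse Puncta Quantification for Synaptome Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies synaptic puncta in multi-channel fluorescence
    micrographs at single-synapse resolution. Provides Laplacian-of-Gaussian
    spot detection with quality and intensity thresholds, montage assembly
    from non-overlapping tile grids, per-region puncta density and intensity
    statistics with replicate aggregation, object-based colocalization and
    juxtaposition analysis between marker channels, marker-fraction tables,
    and row-normalised clustered heatmaps. A synthetic micrograph generator
    with full ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    pheatmap,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
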