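Package: ibbb
Title: Quantifying In Vitro Blood-Brain Barrier Integrity from Assay, Image,
    Expression and Network Data
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multi-stage toolkit for quantifying the integrity of an induced
    in vitro blood-brain barrier (iBBB) formed by brain microvascular
    endothelial monolayers on Transwell inserts. Computes solute permeability
    from lower-chamber tracer accumulation with draw-and-replace dilution
    correction and a series-barrier (blank insert) correction, and
    area-normalized trans-endothelial electrical resistance (TEER) with blank
    subtraction. Quantifies tight-junction protein intensity from perpendicular
    line profiles across cell-cell borders and endothelial surface glycocalyx
    field intensity from confocal-like z-stacks, normalized to matched
    controls. Provides a minimal negative-binomial Wald test with
    median-of-ratios normalization for synthetic count matrices, threshold
    based DEG filtering, deletion-region positive controls, sample PCA and
    hypergeometric gene-set enrichment. Ranks protein-protein interaction
    network nodes by a catalog of centrality measures including diffusion
    degree, with PCA-based selection of the most informative measure, Ward
    clustering with silhouette-optimal k and Jaccard clustering similarity.
    A synthetic-data module generates every pipeline input with known ground
    truth so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    cluster,
    jsonlite,
    yaml,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    tiff,
    deSolve,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'barrier.R'
    'centrality.R'
    'de.R'
    'enrich.R'
    'ibbb-package.R'
    'imaging.R'
    'io.R'
    'pipeline.R'
    'synth-counts.R'
    'synth-images.R'
    'synth-network.R'
    'synth-transwell.R'
    'topology.R'
    'utils.R'
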