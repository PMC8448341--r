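Package: entropyScore
Title: Batch-Robust Transcriptomic Entropy Scoring of Cell Maturation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes a per-cell transcriptomic entropy score -- the Shannon
    entropy of a cell's gene-expression proportions over its top-K (default
    1000) highest-expressed genes -- as a batch-robust metric of
    post-differentiation maturation in single-cell RNA-seq data, with a focus
    on cardiomyocytes and other PSC-derived tissues. Provides the surrounding
    workflow: readers for sparse (MatrixMarket triplet) and dense count
    matrices, gene annotation and biotype curation, correction of
    mitochondrial reads mismapped to nuclear pseudogenes (NUMTs), removal of
    protocol-biased ribosomal protein genes, standardized per-cell and
    per-dataset quality control with group-normalized depth and top-5-gene
    metrics, depth-subsampling robustness analysis, calibration of the
    gene-subsampling level K, UMI-collapse concordance checks, construction of
    staged maturation references, placement of query cells on a reference
    trajectory, and a synthetic-data generator emulating maturation-graded
    narrowing of gene distributions for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    jsonlite,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, QualityControl, Software
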