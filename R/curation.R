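#' Correct mitochondrial reads mismapped to nuclear pseudogenes
#'
#' Nuclear insertions of mitochondrial sequence (NUMTs) are near-identical to
#' the canonical mitochondrial genes, so pipelines that count multi-mapping
#' reads (genomic aligners, transcriptome indices that include pseudogenes)
#' split mitochondrial counts between the true gene and its pseudogene
#' copies. That deflates the apparent mitochondrial fraction and inflates
#' entropy. The correction moves every mapped pseudogene's counts, cell by
#' cell, onto its canonical mitochondrial gene and zeroes the pseudogene row;
#' per-cell depth is conserved exactly.
#'
#' Apply this before biotype filtering — filtering first would destroy the
#' mismapped counts instead of reassigning them.
#'
#' @param x An [EntropyExperiment-class].
#' @param map Named character vector (pseudogene id -> canonical mito gene
#'   id), e.g. from [readPseudogeneMap()]. Map keys absent from the matrix
#'   are skipped with a warning; an absent canonical target is an error.
#' @return `x` with reassigned counts.
#' @export
correctPseudogenes <- function(x, map) {
  if (!length(map)) return(x)
  m <- .countsOf(x)
  keys <- names(map)
  present <- keys %in% rownames(m)
  if (any(!present))
    .warnf("%d pseudogene(s) in the map absent from the matrix (e.g. '%s'); skipped",
           sum(!present), keys[!present][1])
  map <- map[present]
  if (!length(map)) return(x)
  missing_tgt <- setdiff(unique(unname(map)), rownames(m))
  if (length(missing_tgt))
    .stopf("canonical mitochondrial target '%s' absent from the matrix",
           missing_tgt[1])
  gt <- SummarizedExperiment::rowData(x)
  if ("is_mito" %in% colnames(gt)) {
    flags <- gt[unname(map), "is_mito"]
    if (any(flags %in% FALSE))
      .stopf("pseudogene map target '%s' is not flagged mitochondrial",
             unname(map)[which(flags %in% FALSE)[1]])
  }
  m <- methods::as(m, "CsparseMatrix")
  for (tgt in unique(unname(map))) {
    src <- names(map)[unname(map) == tgt]
    add <- if (length(src) == 1L) m[src, ] else Matrix::colSums(m[src, , drop = FALSE])
    m[tgt, ] <- m[tgt, ] + add
  }
  m[names(map), ] <- 0
  m <- Matrix::drop0(m)
  SummarizedExperiment::assay(x, "counts") <- m
  x
}

#' Filter genes by biotype
#'
#' Restricts the matrix to the biotypes used for entropy scoring. The default
#' keep-set is protein-coding, antisense, and lncRNA genes, the transcriptome's
#' key players; pseudogenes, rRNA and other classes are removed. Biotype
#' labels are matched against common annotation synonyms ("lncRNA" also
#' matches "lincRNA"/"long_noncoding").
#'
#' @param x An [EntropyExperiment-class] with gene annotation attached
#'   ([annotateGenes()]), or supply `geneTable`.
#' @param keep Character vector of biotypes to retain. Must be non-empty.
#' @param geneTable Optional gene table if `rowData(x)` lacks `biotype`.
#' @param unannotated `"drop"` (default): genes missing from the annotation
#'   are removed with a message; `"error"`: strict mode, any unannotated gene
#'   aborts.
#' @return The filtered [EntropyExperiment-class].
#' @export
filterBiotypes <- function(x, keep = c("protein_coding", "antisense", "lncRNA"),
                           geneTable = NULL,
                           unannotated = c("drop", "error")) {
  unannotated <- match.arg(unannotated)
  if (!length(keep)) .stopf("the biotype keep-set must not be empty")
  if (!is.null(geneTable)) x <- annotateGenes(x, geneTable)
  rd <- SummarizedExperiment::rowData(x)
  if (!"biotype" %in% colnames(rd))
    .stopf("no biotype annotation; attach a gene table first")
  bt <- rd$biotype
  if (anyNA(bt)) {
    if (unannotated == "error")
      .stopf("gene '%s' has no biotype annotation (strict mode)",
             rownames(x)[which(is.na(bt))[1]])
    message(sprintf("dropping %d unannotated gene(s)", sum(is.na(bt))))
  }
  syn <- list(lncRNA = c("lncRNA", "lincRNA", "long_noncoding", "lncRNAs"),
              antisense = c("antisense", "antisense_RNA"),
              protein_coding = c("protein_coding", "protein coding"))
  expand <- unlist(lapply(keep, function(k) syn[[k]] %||% k))
  x[!is.na(bt) & bt %in% expand, ]
}

#' Remove ribosomal protein-coding genes
#'
#' Ribosomal-protein expression carries a strong library-preparation bias
#' (10x Chromium and STRT-seq libraries show systematically higher fractions
#' than full-length protocols), so these genes are removed before entropy is
#' computed. Per-cell depth decreases by exactly the removed counts.
#'
#' @inheritParams filterBiotypes
#' @return The filtered [EntropyExperiment-class].
#' @seealso [ribosomalFraction()] for the diagnostic the removal is based on.
#' @export
removeRibosomal <- function(x, geneTable = NULL) {
  if (!is.null(geneTable)) x <- annotateGenes(x, geneTable)
  rd <- SummarizedExperiment::rowData(x)
  if (!"is_ribosomal_protein" %in% colnames(rd))
    .stopf("no ribosomal-protein annotation; attach a gene table first")
  x[!(rd$is_ribosomal_protein %in% TRUE), ]
}

#' Per-cell ribosomal-protein count fraction
#'
#' The protocol-bias diagnostic: fraction of each cell's counts on
#' ribosomal-protein genes. Zero-depth cells get `NA`.
#'
#' @inheritParams filterBiotypes
#' @return Named numeric vector in `[0, 1]`, one entry per cell.
#' @export
ribosomalFraction <- function(x, geneTable = NULL) {
  if (!is.null(geneTable)) x <- annotateGenes(x, geneTable)
  rd <- SummarizedExperiment::rowData(x)
  if (!"is_ribosomal_protein" %in% colnames(rd))
    .stopf("no ribosomal-protein annotation; attach a gene table first")
  m <- .countsOf(x)
  tot <- Matrix::colSums(m)
  rib <- Matrix::colSums(m[rd$is_ribosomal_protein %in% TRUE, , drop = FALSE])
  out <- rib / tot
  out[tot == 0] <- NA_real_
  out
}

#' Per-cell mitochondrial count fraction
#'
#' Fraction of each cell's counts on mitochondrial-chromosome genes. Compute
#' this after [correctPseudogenes()] so that mismapped mitochondrial reads
#' are included. Zero-depth cells get `NA`.
#'
#' @inheritParams filterBiotypes
#' @return Named numeric vector in `[0, 1]`, one entry per cell.
#' @export
mitoFraction <- function(x, geneTable = NULL) {
  if (!is.null(geneTable)) x <- annotateGenes(x, geneTable)
  rd <- SummarizedExperiment::rowData(x)
  if (!"is_mito" %in% colnames(rd))
    .stopf("no mitochondrial annotation; attach a gene table first")
  m <- .countsOf(x)
  tot <- Matrix::colSums(m)
  mt <- Matrix::colSums(m[rd$is_mito %in% TRUE, , drop = FALSE])
  out <- mt / tot
  out[tot == 0] <- NA_real_
  out
}
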