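#' @describeIn datatype accessor.
#' @export
setMethod("datatype", "EntropyExperiment", function(x) {
  S4Vectors::metadata(x)$datatype
})

#' @describeIn datatype replacement.
#' @export
setReplaceMethod("datatype", "EntropyExperiment", function(x, value) {
  value <- match.arg(value, c("umi", "reads"))
  S4Vectors::metadata(x)$datatype <- value
  x
})

#' Per-cell library depth and detected genes
#'
#' `depths()` returns total counts per cell; `detectedGenes()` the number of
#' genes with count > 0 per cell.
#'
#' @param x An [EntropyExperiment-class] or a genes x cells counts matrix.
#' @return Named numeric (respectively integer) vector, one entry per cell.
#' @export
depths <- function(x) {
  Matrix::colSums(.countsOf(x))
}

#' @rdname depths
#' @export
detectedGenes <- function(x) {
  Matrix::colSums(.countsOf(x) > 0)
}

.countsOf <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else x
}

#' Attach per-gene annotation to an EntropyExperiment
#'
#' Matches a gene table (see [readGeneTable()]) to the experiment's genes by
#' `gene_id` and stores it in `rowData`. Genes absent from the table receive
#' `NA` annotation; downstream curation decides how to treat them (see
#' [filterBiotypes()]).
#'
#' @param x An [EntropyExperiment-class].
#' @param geneData `DataFrame`/`data.frame` with at least a `gene_id` column.
#' @return `x` with populated `rowData`.
#' @export
annotateGenes <- function(x, geneData) {
  geneData <- as.data.frame(geneData)
  if (!"gene_id" %in% colnames(geneData))
    .stopf("gene annotation must have a 'gene_id' column")
  if (anyDuplicated(geneData$gene_id))
    .stopf("duplicated gene_id in gene annotation: '%s'",
           geneData$gene_id[duplicated(geneData$gene_id)][1])
  idx <- match(rownames(x), geneData$gene_id)
  rd <- geneData[idx, , drop = FALSE]
  rd$gene_id <- rownames(x)
  rownames(rd) <- rownames(x)
  SummarizedExperiment::rowData(x) <- S4Vectors::DataFrame(rd)
  x
}

#' Attach per-cell metadata to an EntropyExperiment
#'
#' Matches per-cell metadata (see [readCellMetadata()]) by `cell_id`. Every
#' cell must appear in the metadata exactly once; each cell then belongs to
#' exactly one (study_id, timepoint_label) group.
#'
#' @param x An [EntropyExperiment-class].
#' @param cellData `DataFrame`/`data.frame` with a `cell_id` column.
#' @return `x` with populated `colData`.
#' @export
annotateCells <- function(x, cellData) {
  cellData <- as.data.frame(cellData)
  if (!"cell_id" %in% colnames(cellData))
    .stopf("cell metadata must have a 'cell_id' column")
  if (anyDuplicated(cellData$cell_id))
    .stopf("duplicated cell_id in metadata: '%s'",
           cellData$cell_id[duplicated(cellData$cell_id)][1])
  idx <- match(colnames(x), cellData$cell_id)
  if (anyNA(idx))
    .stopf("cell(s) missing from metadata, e.g. '%s'",
           colnames(x)[which(is.na(idx))[1]])
  cd <- cellData[idx, , drop = FALSE]
  rownames(cd) <- colnames(x)
  SummarizedExperiment::colData(x) <- S4Vectors::DataFrame(cd)
  x
}

#' @describeIn EntropyExperiment compact display.
#' @param object An `EntropyExperiment`.
#' @export
setMethod("show", "EntropyExperiment", function(object) {
  cat(sprintf("EntropyExperiment: %d genes x %d cells [%s]\n",
              nrow(object), ncol(object), datatype(object)))
  d <- depths(object)
  if (length(d))
    cat(sprintf("  depth: median %s (range %s-%s); detected genes: median %s\n",
                format(median(d)), format(min(d)), format(max(d)),
                format(median(detectedGenes(object)))))
  rd <- SummarizedExperiment::rowData(object)
  if ("biotype" %in% colnames(rd))
    cat(sprintf("  annotated genes: %d; mito: %d; ribosomal: %d\n",
                sum(!is.na(rd$biotype)),
                sum(rd$is_mito %in% TRUE), sum(rd$is_ribosomal_protein %in% TRUE)))
  cd <- SummarizedExperiment::colData(object)
  if ("study_id" %in% colnames(cd))
    cat(sprintf("  studies: %d; timepoints: %d\n",
                length(unique(cd$study_id)),
                length(unique(cd$timepoint_label))))
  invisible(NULL)
})

#' @describeIn MaturationReference compact display.
#' @param object A `MaturationReference`.
#' @export
setMethod("show", "MaturationReference", function(object) {
  st <- object@stages
  cat(sprintf("MaturationReference: %d stages (%s), %d cells, k = %s\n",
              nrow(st), paste(unique(st$species), collapse = "/"),
              sum(st$n_cells),
              format(object@scoreParams$k %||% NA)))
  wob <- which(diff(st$median_score) > 0)
  if (length(wob))
    cat(sprintf("  note: median score increases at %d stage transition(s)\n",
                length(wob)))
  print(as.data.frame(st))
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stage table of a MaturationReference
#'
#' @param x A [MaturationReference-class].
#' @return A `DataFrame` of ordered stages with entropy-score summaries.
#' @export
referenceStages <- function(x) {
  stopifnot(is(x, "MaturationReference"))
  x@stages
}
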