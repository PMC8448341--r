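#' EntropyExperiment: counts plus annotation for entropy scoring
#'
#' `EntropyExperiment` extends
#' \linkS4class{SingleCellExperiment} with validity
#' guarantees required by the entropy-score workflow: a `"counts"` assay of
#' non-negative integer counts (raw reads or UMIs, never normalized values),
#' unique gene and cell identifiers, and a declared `datatype` (`"umi"` or
#' `"reads"`). Gene annotation (biotype, mitochondrial flag, ribosomal-protein
#' flag, pseudogene parent) lives in `rowData`; per-cell metadata (study,
#' timepoint, protocol) lives in `colData`.
#'
#' Internally genes are rows and cells are columns, the Bioconductor
#' convention; readers normalize on-disk orientation on ingest.
#'
#' @slot ... inherited from \linkS4class{SingleCellExperiment}.
#'
#' @seealso [EntropyExperiment()] the constructor; [readCounts()].
#' @aliases EntropyExperiment-class
#' @exportClass EntropyExperiment
setClass("EntropyExperiment", contains = "SingleCellExperiment")

setValidity("EntropyExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "an assay named 'counts' is required")
  else {
    cm <- SummarizedExperiment::assay(object, "counts")
    bad <- .checkCountValues(cm)
    if (!is.null(bad)) msg <- c(msg, bad)
  }
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene_ids (rownames) and cell_ids (colnames) are required")
  else {
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, sprintf("duplicated gene_id: '%s'",
                            rownames(object)[duplicated(rownames(object))][1]))
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, sprintf("duplicated cell_id: '%s'",
                            colnames(object)[duplicated(colnames(object))][1]))
  }
  dt <- S4Vectors::metadata(object)$datatype
  if (is.null(dt) || !dt %in% c("umi", "reads"))
    msg <- c(msg, "metadata(object)$datatype must be 'umi' or 'reads'")
  if (length(msg)) msg else TRUE
})

#' Construct an EntropyExperiment
#'
#' @param counts A genes x cells matrix (dense or `dgCMatrix`) of non-negative
#'   integer counts, with gene ids as rownames and cell ids as colnames.
#' @param geneData Optional `DataFrame`/`data.frame` of per-gene annotation
#'   (as produced by [readGeneTable()]); matched to `rownames(counts)` by its
#'   `gene_id` column. Genes absent from the table get `NA` annotation.
#' @param cellData Optional `DataFrame`/`data.frame` of per-cell metadata (as
#'   produced by [readCellMetadata()]); matched by `cell_id`.
#' @param datatype `"umi"` (molecule counts) or `"reads"` (pre-collapse read
#'   counts).
#'
#' @return A validated [EntropyExperiment-class] object.
#' @examples
#' m <- matrix(rpois(12, 5), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
#' ee <- EntropyExperiment(m, datatype = "umi")
#' depths(ee)
#' @export
EntropyExperiment <- function(counts, geneData = NULL, cellData = NULL,
                              datatype = c("umi", "reads")) {
  datatype <- match.arg(datatype)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("counts must carry gene ids as rownames and cell ids as colnames")
  bad <- .checkCountValues(counts)
  if (!is.null(bad)) .stopf("%s", bad)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    metadata = list(datatype = datatype))
  ee <- methods::new("EntropyExperiment", sce)
  if (!is.null(geneData)) ee <- annotateGenes(ee, geneData)
  if (!is.null(cellData)) ee <- annotateCells(ee, cellData)
  validObject(ee)
  ee
}

#' MaturationReference: a staged entropy-score reference trajectory
#'
#' Ordered maturation stages (e.g. embryonic days through adult) with
#' per-stage entropy-score summaries, used to place query cells on an in vivo
#' trajectory. Stages are strictly ordered by `timepoint_rank` within each
#' species. Median scores are expected to decrease with maturation but this
#' is not enforced; non-monotone stretches are reported by `show()`.
#'
#' @slot stages A `DataFrame` with columns `stage_label`, `timepoint_rank`,
#'   `species`, `median_score`, `q25`, `q75`, `n_cells`, `n_studies`.
#' @slot scoreParams List recording how scores were computed (`k`, `log_base`).
#' @slot version Character; serialization format version.
#'
#' @seealso [buildReference()], [stageCells()].
#' @aliases MaturationReference-class
#' @exportClass MaturationReference
setClass("MaturationReference",
  representation(stages = "DataFrame", scoreParams = "list",
                 version = "character"))

setValidity("MaturationReference", function(object) {
  st <- object@stages
  need <- c("stage_label", "timepoint_rank", "species", "median_score",
            "q25", "q75", "n_cells", "n_studies")
  miss <- setdiff(need, colnames(st))
  if (length(miss))
    return(sprintf("stages is missing column(s): %s",
                   paste(miss, collapse = ", ")))
  for (sp in unique(st$species)) {
    r <- st$timepoint_rank[st$species == sp]
    if (is.unsorted(r, strictly = TRUE))
      return(sprintf(
        "stages must be strictly ordered by timepoint_rank within species '%s'",
        sp))
  }
  TRUE
})
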