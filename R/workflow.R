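#' Run the full entropy-score workflow
#'
#' Wires the pipeline end to end in its canonical order: pseudogene
#' correction, then cell QC on the corrected matrix (mitochondrial and top-5
#' signal intact), then biotype filtering and ribosomal removal, then top-K
#' entropy scoring of the QC-passed cells. Every tunable lands in the run
#' manifest together with input checksums and the package version, so a run
#' is reproducible from its manifest alone.
#'
#' @param x An [EntropyExperiment-class].
#' @param geneTable Gene annotation ([readGeneTable()]); may be omitted if
#'   already attached.
#' @param metadata Per-cell metadata ([readCellMetadata()]); may be omitted
#'   if already attached via [annotateCells()].
#' @param pseudogeneMap Optional named vector ([readPseudogeneMap()]).
#' @param k Top-gene pool size (default 1000).
#' @param log_base Logarithm base for scores (default natural log).
#' @param biotypes_keep Biotype keep-set (see [filterBiotypes()]).
#' @param depth_cut,top5_cut,min_genes Cell-filter thresholds
#'   (see [filterCells()]).
#' @param seed Seed recorded in the manifest (the deterministic pipeline
#'   itself draws no random numbers; the seed is for provenance of upstream
#'   simulation or subsampling steps).
#' @return A list: `scores` (`DataFrame`, QC-passed cells only), `qc`
#'   (normalized per-cell QC), `audit` (cell-filter audit), `experiment`
#'   (the curated [EntropyExperiment-class] that was scored), `manifest`
#'   (named list of every parameter plus provenance).
#' @export
runWorkflow <- function(x, geneTable = NULL, metadata = NULL,
                        pseudogeneMap = NULL, k = 1000, log_base = exp(1),
                        biotypes_keep = c("protein_coding", "antisense",
                                          "lncRNA"),
                        depth_cut = -0.5, top5_cut = 1.3, min_genes = 1000,
                        seed = NULL) {
  if (!is.null(geneTable)) x <- annotateGenes(x, geneTable)
  if (!is.null(metadata)) x <- annotateCells(x, metadata)
  md <- .cellMeta(x, NULL)
  need <- c("study_id", "timepoint_label")
  if (length(setdiff(need, colnames(md))))
    .stopf("[qc] cell metadata with study_id and timepoint_label is required")
  checksum <- .checksum(.countsOf(x))
  ## 1. pseudogene correction
  if (!is.null(pseudogeneMap) && length(pseudogeneMap))
    x <- correctPseudogenes(x, pseudogeneMap)
  ## 2. cell QC on the corrected, unfiltered matrix
  qc <- cellQCMetrics(x)
  qc <- normalizeQC(qc, md)
  flt <- filterCells(qc, depth_cut = depth_cut, top5_cut = top5_cut,
                     min_genes = min_genes)
  ## 3. gene curation
  x <- filterBiotypes(x, keep = biotypes_keep)
  x <- removeRibosomal(x)
  ## 4. scoring of retained cells
  kept <- x[, flt$retained]
  scores <- entropyScores(kept, k = k, log_base = log_base)
  manifest <- list(
    package = "entropyScore",
    version = as.character(packageVersion("entropyScore")),
    input_genes = checksum$dim[1],
    input_cells = checksum$dim[2],
    input_total_counts = checksum$total,
    input_checksum = checksum$md5,
    datatype = datatype(x),
    pseudogene_map_size = length(pseudogeneMap),
    biotypes_keep = biotypes_keep,
    k = k, log_base = log_base,
    depth_cut = depth_cut, top5_cut = top5_cut, min_genes = min_genes,
    seed = seed,
    n_cells_retained = length(flt$retained),
    timestamp = format(Sys.time(), tz = "UTC"))
  list(scores = scores, qc = qc, audit = flt$audit, experiment = kept,
       manifest = manifest)
}

## md5 of the serialized counts via a temp file (provenance, not security).
.checksum <- function(m) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(dimnames(m), methods::as(m, "CsparseMatrix")@x), f)
  list(md5 = unname(tools::md5sum(f)), dim = dim(m), total = sum(m))
}
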