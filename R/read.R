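#' Read a count matrix into an EntropyExperiment
#'
#' Supports the 10x-style MatrixMarket triplet (matrix.mtx + barcodes.tsv +
#' features.tsv, plain or gzipped) and dense delimited tables. Counts must be
#' raw integers (reads or UMIs); normalized/TPM input is rejected because the
#' within-cell gene proportions and the depth-subsampling analysis are defined
#' on counts.
#'
#' On-disk orientation is normalized: internally genes are rows and cells are
#' columns. For dense tables the default assumes cells are rows (one row per
#' cell barcode); set `orientation = "genes_by_cells"` for the transpose. The
#' MTX triplet follows the 10x convention (features are matrix rows).
#'
#' @param path For `"mtx_triplet"`, the directory containing the triplet (or
#'   the path of the `.mtx` file itself); for `"dense_delimited"`, the table
#'   file (TSV or CSV, autodetected from content).
#' @param format `"mtx_triplet"` or `"dense_delimited"`.
#' @param datatype `"umi"` or `"reads"`.
#' @param orientation Dense tables only: `"cells_by_genes"` (default) or
#'   `"genes_by_cells"`.
#' @return An [EntropyExperiment-class].
#' @seealso [writeCounts()] for the inverse.
#' @export
readCounts <- function(path, format = c("mtx_triplet", "dense_delimited"),
                       datatype = c("umi", "reads"),
                       orientation = c("cells_by_genes", "genes_by_cells")) {
  format <- match.arg(format)
  datatype <- match.arg(datatype)
  orientation <- match.arg(orientation)
  if (format == "mtx_triplet") {
    .readMtxTriplet(path, datatype)
  } else {
    .readDense(path, datatype, orientation)
  }
}

.findCompanion <- function(dir, stems) {
  for (stem in stems) for (ext in c("", ".gz")) {
    f <- file.path(dir, paste0(stem, ext))
    if (file.exists(f)) return(f)
  }
  .stopf("missing companion file in '%s': expected one of %s",
         dir, paste(stems, collapse = ", "))
}

.readMtxTriplet <- function(path, datatype) {
  dir <- if (dir.exists(path)) path else dirname(path)
  mtx <- if (!dir.exists(path)) path
         else .findCompanion(dir, c("matrix.mtx"))
  bc  <- .findCompanion(dir, c("barcodes.tsv"))
  ft  <- .findCompanion(dir, c("features.tsv", "genes.tsv"))
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) .stopf("malformed MatrixMarket file '%s': %s",
                                           mtx, conditionMessage(e)))
  barcodes <- readLines(bc)
  features <- read.delim(ft, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(m) != nrow(features))
    .stopf("feature file has %d records but matrix has %d rows",
           nrow(features), nrow(m))
  if (ncol(m) != length(barcodes))
    .stopf("barcode file has %d records but matrix has %d columns",
           length(barcodes), ncol(m))
  if (anyDuplicated(features[[1]]))
    .stopf("duplicated gene_id in '%s': '%s'", ft,
           features[[1]][duplicated(features[[1]])][1])
  if (anyDuplicated(barcodes))
    .stopf("duplicated cell barcode in '%s': '%s'", bc,
           barcodes[duplicated(barcodes)][1])
  dimnames(m) <- list(features[[1]], barcodes)
  bad <- .checkCountValues(m)
  if (!is.null(bad)) .stopf("in '%s': %s", mtx, bad)
  EntropyExperiment(m, datatype = datatype)
}

.readDense <- function(path, datatype, orientation) {
  if (!file.exists(path)) .stopf("file not found: '%s'", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.delim(path, sep = sep, header = TRUE, row.names = 1L,
                    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    nonnum <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                    !is.na(m), arr.ind = TRUE)
    if (nrow(nonnum))
      .stopf("non-numeric entry at row '%s', column '%s' of '%s'",
             rownames(tab)[nonnum[1, 1]], colnames(tab)[nonnum[1, 2]], path)
    .stopf("non-numeric entries in '%s'", path)
  }
  frac <- which(m != round(m), arr.ind = TRUE)
  if (nrow(frac))
    .stopf(
      "non-integer count %s at row '%s', column '%s' of '%s' (raw counts required)",
      format(m[frac[1, , drop = FALSE]]), rownames(tab)[frac[1, 1]],
      colnames(tab)[frac[1, 2]], path)
  if (orientation == "cells_by_genes") m <- t(m)
  if (anyDuplicated(rownames(m)))
    .stopf("duplicated gene_id '%s' in '%s'",
           rownames(m)[duplicated(rownames(m))][1], path)
  if (anyDuplicated(colnames(m)))
    .stopf("duplicated cell_id '%s' in '%s'",
           colnames(m)[duplicated(colnames(m))][1], path)
  EntropyExperiment(m, datatype = datatype)
}

#' Write a count matrix
#'
#' Writes either an MTX triplet (matrix.mtx / barcodes.tsv / features.tsv in
#' a directory) or a dense delimited table. Round-trips through
#' [readCounts()] exactly.
#'
#' @param x An [EntropyExperiment-class] or genes x cells counts matrix.
#' @param path Directory (mtx_triplet) or file (dense_delimited).
#' @param format `"mtx_triplet"` or `"dense_delimited"`.
#' @param orientation Dense output orientation (see [readCounts()]).
#' @return `path`, invisibly.
#' @export
writeCounts <- function(x, path, format = c("mtx_triplet", "dense_delimited"),
                        orientation = c("cells_by_genes", "genes_by_cells")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  m <- .countsOf(x)
  if (format == "mtx_triplet") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
    write.table(data.frame(V1 = rownames(m), V2 = rownames(m)),
                file.path(path, "features.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    dm <- as.matrix(m)
    if (orientation == "cells_by_genes") dm <- t(dm)
    df <- data.frame(id = rownames(dm), dm, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read per-gene annotation
#'
#' Builds the gene table driving curation: biotype filtering, mitochondrial
#' flagging, ribosomal-protein flagging, and pseudogene-parent validation.
#' `is_mito` is set from the chromosome (dialects `"MT"`, `"chrM"`, `"chrMT"`
#' are all accepted). Ribosomal-protein genes are flagged from symbol
#' patterns — default `^Rp[sl]` (mouse) and `^RP[SL]` (human), case-sensitive,
#' which deliberately exclude mitochondrial ribosomal genes (`Mrpl`/`Mrps`) —
#' or from an explicit id/symbol list via `ribosomal_genes`.
#'
#' @param path A GTF file (gene-level records with `gene_id` and
#'   `gene_biotype`/`gene_type` attributes) or a flat delimited table with
#'   columns `gene_id`, `biotype`, and optionally `gene_symbol`, `chromosome`.
#' @param format `"gtf"` or `"flat_table"`.
#' @param ribosomal_patterns Character vector of regular expressions applied
#'   to gene symbols.
#' @param ribosomal_genes Optional explicit character vector of gene ids or
#'   symbols to flag as ribosomal-protein genes (overrides patterns).
#' @return A `DataFrame` with columns `gene_id`, `gene_symbol`, `biotype`,
#'   `chromosome`, `is_mito`, `is_ribosomal_protein`, `pseudogene_parent`
#'   (all `NA` parents; populate from a pseudogene map if desired).
#' @export
readGeneTable <- function(path, format = c("gtf", "flat_table"),
                          ribosomal_patterns = c("^Rp[sl]", "^RP[SL]"),
                          ribosomal_genes = NULL) {
  format <- match.arg(format)
  if (format == "gtf") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      .stopf("reading GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gtf")
    md <- S4Vectors::mcols(gr)
    keep <- if ("type" %in% colnames(md)) md$type == "gene" else
      rep(TRUE, length(gr))
    gr <- gr[keep]
    md <- S4Vectors::mcols(gr)
    if (!"gene_id" %in% colnames(md))
      .stopf("GTF '%s' has no gene_id attribute", path)
    bt <- if ("gene_biotype" %in% colnames(md)) md$gene_biotype
          else if ("gene_type" %in% colnames(md)) md$gene_type
          else NULL
    if (is.null(bt) || anyNA(bt))
      .stopf("GTF '%s' lacks gene_biotype/gene_type (first offending gene: %s)",
             path,
             if (is.null(bt)) md$gene_id[1] else md$gene_id[which(is.na(bt))[1]])
    tab <- data.frame(
      gene_id = md$gene_id,
      gene_symbol = if ("gene_name" %in% colnames(md)) md$gene_name
                    else md$gene_id,
      biotype = bt,
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      stringsAsFactors = FALSE)
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    tab <- read.delim(path, sep = sep, header = TRUE,
                      stringsAsFactors = FALSE)
    if (!"gene_id" %in% colnames(tab))
      .stopf("gene table '%s' lacks a gene_id column", path)
    if (!"biotype" %in% colnames(tab))
      .stopf("gene table '%s' lacks a biotype column", path)
    if (!"gene_symbol" %in% colnames(tab)) tab$gene_symbol <- tab$gene_id
    if (!"chromosome" %in% colnames(tab)) tab$chromosome <- NA_character_
  }
  if (anyDuplicated(tab$gene_id))
    .stopf("duplicated gene_id '%s' in '%s'",
           tab$gene_id[duplicated(tab$gene_id)][1], path)
  tab$is_mito <- .isMitoChrom(tab$chromosome)
  if (!is.null(ribosomal_genes)) {
    tab$is_ribosomal_protein <- tab$gene_id %in% ribosomal_genes |
      tab$gene_symbol %in% ribosomal_genes
  } else {
    hit <- rep(FALSE, nrow(tab))
    for (p in ribosomal_patterns) hit <- hit | grepl(p, tab$gene_symbol)
    tab$is_ribosomal_protein <- hit
  }
  if (!"pseudogene_parent" %in% colnames(tab))
    tab$pseudogene_parent <- NA_character_
  S4Vectors::DataFrame(
    tab[, c("gene_id", "gene_symbol", "biotype", "chromosome", "is_mito",
            "is_ribosomal_protein", "pseudogene_parent")])
}

#' Read a pseudogene-to-mitochondrial-gene map
#'
#' Two-column delimited file mapping nuclear mitochondrial pseudogene ids
#' (NUMTs) to the canonical mitochondrial gene their reads cross-map with.
#' When a gene table is supplied, every map target must be a mitochondrial
#' gene — a nuclear target signals a bad map and is an error, never silently
#' accepted.
#'
#' @param path Two-column TSV/CSV (pseudogene id, canonical mito gene id); a
#'   header line is autodetected. An empty file yields an empty map (the
#'   correction then reduces to the identity).
#' @param geneTable Optional gene table from [readGeneTable()] for
#'   validation.
#' @return Named character vector: `names` are pseudogene ids, values the
#'   canonical mitochondrial gene ids.
#' @seealso [correctPseudogenes()]
#' @export
readPseudogeneMap <- function(path, geneTable = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(setNames(character(0), character(0)))
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  tab <- read.delim(text = lines, sep = sep, header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    .stopf("pseudogene map '%s' must have two columns", path)
  ## drop an optional header
  if (tolower(tab[1, 1]) %in% c("pseudogene", "pseudogene_id", "gene_id"))
    tab <- tab[-1, , drop = FALSE]
  map <- setNames(as.character(tab[[2]]), as.character(tab[[1]]))
  if (anyDuplicated(names(map)))
    .stopf("pseudogene '%s' mapped twice in '%s'",
           names(map)[duplicated(names(map))][1], path)
  if (!is.null(geneTable)) validatePseudogeneMap(map, geneTable)
  map
}

#' @rdname readPseudogeneMap
#' @param map Named character vector as returned by `readPseudogeneMap()`.
#' @export
validatePseudogeneMap <- function(map, geneTable) {
  if (!length(map)) return(invisible(map))
  gt <- as.data.frame(geneTable)
  tgt <- match(unname(map), gt$gene_id)
  if (anyNA(tgt))
    .stopf("pseudogene map target '%s' not present in the gene table",
           unname(map)[which(is.na(tgt))[1]])
  notmito <- which(!gt$is_mito[tgt])
  if (length(notmito))
    .stopf("pseudogene map target '%s' is not a mitochondrial gene",
           unname(map)[notmito[1]])
  invisible(map)
}

#' Read per-cell metadata
#'
#' CSV/TSV with required columns `cell_id`, `study_id`, `timepoint_label`,
#' `timepoint_rank` and optional `species`, `protocol`, `datatype`,
#' `celltype_label`. `timepoint_rank` is the ordinal developmental order
#' within a species (it need not be numeric time); within each
#' (species, timepoint_label) pair the rank must be constant.
#'
#' @param path Delimited file.
#' @return A `DataFrame`, one row per cell.
#' @export
readCellMetadata <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  need <- c("cell_id", "study_id", "timepoint_label", "timepoint_rank")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    .stopf("cell metadata '%s' is missing column(s): %s", path,
           paste(miss, collapse = ", "))
  if (anyDuplicated(tab$cell_id))
    .stopf("duplicated cell_id '%s' in '%s'",
           tab$cell_id[duplicated(tab$cell_id)][1], path)
  if (!is.numeric(tab$timepoint_rank))
    .stopf("timepoint_rank must be numeric in '%s'", path)
  sp <- if ("species" %in% colnames(tab)) tab$species else "unspecified"
  chk <- unique(data.frame(sp = sp, label = tab$timepoint_label,
                           rank = tab$timepoint_rank))
  dup <- chk[duplicated(chk[, c("sp", "label")]), ]
  if (nrow(dup))
    .stopf("timepoint label '%s' has inconsistent timepoint_rank", dup$label[1])
  S4Vectors::DataFrame(tab)
}
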