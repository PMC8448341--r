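## Small fixtures shared across test files. Everything is built in code.

.counts <- function(x) SummarizedExperiment::assay(x, "counts")

## A named genes x cells matrix from a list of named cell count vectors.
toyMatrix <- function(cells) {
  genes <- sort(unique(unlist(lapply(cells, names))))
  m <- matrix(0, nrow = length(genes), ncol = length(cells),
              dimnames = list(genes, names(cells)))
  for (cn in names(cells)) m[names(cells[[cn]]), cn] <- cells[[cn]]
  m
}

## Minimal gene table covering arbitrary gene ids; mito/ribo flags from the
## id itself ("mt-" prefix, "Rps"/"Rpl" prefix), pseudogenes from "-ps".
toyGeneTable <- function(gene_ids, biotype = NULL) {
  if (is.null(biotype)) {
    biotype <- rep("protein_coding", length(gene_ids))
    biotype[grepl("-ps$", gene_ids)] <- "pseudogene"
  }
  S4Vectors::DataFrame(
    gene_id = gene_ids,
    gene_symbol = gene_ids,
    biotype = biotype,
    chromosome = ifelse(grepl("^mt-", gene_ids), "MT", "1"),
    is_mito = grepl("^mt-", gene_ids),
    is_ribosomal_protein = grepl("^Rp[sl]", gene_ids),
    pseudogene_parent = NA_character_)
}

toyExperiment <- function(cells, datatype = "umi", biotype = NULL) {
  m <- toyMatrix(cells)
  EntropyExperiment(m, geneData = toyGeneTable(rownames(m), biotype),
                    datatype = datatype)
}

toyMetadata <- function(cell_ids, study = "s1", timepoint = "t1", rank = 1L,
                        species = "mouse") {
  S4Vectors::DataFrame(cell_id = cell_ids, study_id = study,
                       timepoint_label = timepoint, timepoint_rank = rank,
                       species = species)
}

## Independent brute-force oracle for the entropy score of one cell:
## top-k selection via explicit ordering, renormalization, direct summation.
bruteForceScore <- function(counts, k, log_base = exp(1)) {
  counts <- counts[counts > 0]
  ord <- order(-counts, names(counts))
  top <- counts[ord][seq_len(min(k, length(counts)))]
  p <- top / sum(top)
  -sum(p * log(p)) / log(log_base)
}

## A small fast synthetic series used by several files.
smallSeries <- function(seed = 11, cells_per_stage = 25, n_genes = 1500,
                        ...) {
  simulateMaturationSeries(
    syntheticSpec(cells_per_stage = cells_per_stage, n_genes = n_genes,
                  seed = seed, ...))
}
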