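#' Within-cell gene proportions
#'
#' Converts a single cell's count vector to the probability of selecting each
#' gene: counts divided by the cell's total counts.
#'
#' @param counts Numeric vector of non-negative integer counts for one cell.
#' @return Probability vector summing to 1.
#' @examples
#' geneProbabilities(c(2, 3, 5))
#' @export
geneProbabilities <- function(counts) {
  bad <- .checkCountValues(counts)
  if (!is.null(bad)) .stopf("%s", bad)
  tot <- sum(counts)
  if (tot == 0)
    .stopf("all-zero count vector: the cell has no counts and should have been removed by QC")
  counts / tot
}

#' Shannon entropy of a probability vector
#'
#' \eqn{S = -\sum_i P_i \log P_i}, with \eqn{0 \log 0 = 0}. The value lies in
#' `[0, log(length(p))]` in the chosen base.
#'
#' @param p Probability vector (non-negative, summing to 1 within `1e-6`).
#' @param log_base Base of the logarithm; the default `exp(1)` reports nats.
#' @return Non-negative numeric scalar.
#' @examples
#' shannonEntropy(rep(0.25, 4))      # log(4)
#' shannonEntropy(c(1, 0, 0))        # 0
#' @export
shannonEntropy <- function(p, log_base = exp(1)) {
  if (any(is.na(p)) || any(p < 0))
    .stopf("probabilities must be non-negative and non-missing")
  if (abs(sum(p) - 1) > 1e-6)
    .stopf("probabilities must sum to 1 (got %s)", format(sum(p)))
  pos <- p[p > 0]
  -sum(pos * log(pos, base = log_base))
}

#' Top-K highest-expressed-gene subset of a cell
#'
#' Retains the `k` genes with the largest counts in this cell. Ties at the
#' k-th position are broken by lexicographic gene id, making the subset
#' deterministic across platforms. Genes with zero counts are never part of
#' the subset; if the cell detects fewer than `k` genes, all detected genes
#' are kept and the shortfall is visible as `length(result) < k`.
#'
#' @param counts Named numeric vector of counts for one cell (names are gene
#'   ids).
#' @param k Positive integer.
#' @return Named numeric vector over at most `k` genes, ordered by
#'   decreasing count (ties lexicographic).
#' @examples
#' topKSubset(c(A = 5, B = 3, C = 3, D = 1), k = 2)   # A and B
#' @export
topKSubset <- function(counts, k) {
  if (length(k) != 1L || is.na(k) || k < 1)
    .stopf("k must be a positive integer")
  if (is.null(names(counts)))
    .stopf("counts must be named by gene id")
  detected <- counts[counts > 0]
  ord <- order(-detected, names(detected), method = "radix")
  detected[ord][seq_len(min(k, length(detected)))]
}

## Entropies at one or more k from a cell's nonzero counts. Proportions are
## renormalized within each top-k subset and computed as exact count ratios,
## which makes the score bit-reproducible under uniform integer scaling of a
## cell (c*v / c*T rounds to the same double as v / T). Which of several tied
## boundary genes enters the subset does not change the value, so no
## tie-breaking is needed here.
.entropyAtK <- function(nonzero, ks, log_base = exp(1)) {
  v <- sort(nonzero, decreasing = TRUE)
  lb <- log(log_base)
  vapply(pmin(ks, length(v)), function(k) {
    top <- v[seq_len(k)]
    p <- top / sum(top)
    -sum(p * log(p)) / lb
  }, numeric(1))
}

#' Per-cell transcriptomic entropy score
#'
#' The maturation metric: for each cell independently, subset the top `k`
#' highest-expressed genes (default 1000), renormalize the gene proportions
#' within that subset, and compute the Shannon entropy. Restricting the
#' summation to a fixed number of genes standardizes the score against
#' protocol sensitivity differences; scores are invariant to uniform count
#' scaling (hence to PCR duplication) and to any change below the top-k
#' boundary.
#'
#' The input should have passed gene curation ([correctPseudogenes()],
#' [filterBiotypes()], [removeRibosomal()]) and cell QC; zero-depth cells are
#' an error. Cells detecting fewer than `k` genes are scored over all
#' detected genes and flagged via `n_genes_pooled < k_requested`.
#'
#' @param x An [EntropyExperiment-class], or a genes x cells counts matrix
#'   (dense or sparse) with dimnames.
#' @param k Number of top genes to pool (default 1000).
#' @param log_base Logarithm base; default natural log (scores in nats).
#' @param ... Passed between methods.
#' @return A `DataFrame` with one row per cell: `cell_id`, `score`,
#'   `k_requested`, `n_genes_pooled`, `depth`, `n_genes`, `low_coverage`
#'   (TRUE when fewer than `k` genes were detected), `log_base`.
#' @examples
#' m <- matrix(c(10, 10, 10, 30, 0, 0), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("c1", "c2")))
#' entropyScores(m, k = 3)
#' @rdname entropyScores
#' @aliases entropyScores,EntropyExperiment-method entropyScores,ANY-method
#' @export
setMethod("entropyScores", "EntropyExperiment",
          function(x, k = 1000, log_base = exp(1), ...) {
  .entropyScoresMatrix(.countsOf(x), k = k, log_base = log_base)
})

#' @rdname entropyScores
#' @export
setMethod("entropyScores", "ANY", function(x, k = 1000, log_base = exp(1), ...) {
  .entropyScoresMatrix(x, k = k, log_base = log_base)
})

.entropyScoresMatrix <- function(m, k = 1000, log_base = exp(1)) {
  if (length(k) != 1L || is.na(k) || k < 1) .stopf("k must be a positive integer")
  if (is.null(colnames(m))) .stopf("counts must carry cell ids as colnames")
  bad <- .checkCountValues(m)
  if (!is.null(bad)) .stopf("%s", bad)
  m <- Matrix::drop0(methods::as(methods::as(methods::as(m, "dMatrix"),
                                             "generalMatrix"), "CsparseMatrix"))
  nz <- .perCellNonzero(m)
  depth <- Matrix::colSums(m)
  ngene <- lengths(nz)
  if (any(depth == 0))
    .stopf("cell '%s' has zero depth; remove it before scoring",
           colnames(m)[which(depth == 0)[1]])
  score <- vapply(nz, function(v) .entropyAtK(v, k, log_base), numeric(1))
  pooled <- pmin(as.integer(k), ngene)
  S4Vectors::DataFrame(
    cell_id = colnames(m),
    score = unname(score),
    k_requested = as.integer(k),
    n_genes_pooled = as.integer(pooled),
    depth = unname(depth),
    n_genes = as.integer(ngene),
    low_coverage = unname(ngene < k),
    log_base = log_base,
    row.names = colnames(m))
}

## List of per-cell nonzero count vectors from a CsparseMatrix.
.perCellNonzero <- function(m) {
  cells <- rep.int(seq_len(ncol(m)), diff(m@p))
  out <- split(m@x, factor(cells, levels = seq_len(ncol(m))))
  names(out) <- colnames(m)
  out
}
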