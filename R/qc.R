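#' Per-cell quality-control metrics
#'
#' Raw per-cell summaries used by the standardized QC: library depth, number
#' of detected genes, the fraction of depth in the cell's five
#' highest-expressed genes (`top5_fraction`; lysed or degraded cells are
#' dominated by a few transcripts), and the mitochondrial fraction. Compute
#' this after pseudogene correction (which affects `mito_fraction`) and
#' before ribosomal removal — ribosomal counts are genuine signal for QC
#' purposes even though they are excluded from the entropy itself.
#'
#' Zero-depth cells are never dropped silently: their fraction metrics are
#' `NA` and they fail every downstream filter.
#'
#' @param x An [EntropyExperiment-class] (or genes x cells counts matrix).
#' @param geneTable Optional gene table; required for `mito_fraction` when
#'   `rowData(x)` lacks `is_mito`.
#' @return A `DataFrame`: `cell_id`, `depth`, `n_genes`, `top5_fraction`,
#'   `mito_fraction`.
#' @export
cellQCMetrics <- function(x, geneTable = NULL) {
  if (!is.null(geneTable) && is(x, "EntropyExperiment"))
    x <- annotateGenes(x, geneTable)
  m <- Matrix::drop0(methods::as(.countsOf(x), "CsparseMatrix"))
  depth <- Matrix::colSums(m)
  nz <- .perCellNonzero(m)
  top5 <- vapply(nz, function(v) {
    if (!length(v)) return(NA_real_)
    sum(sort(v, decreasing = TRUE)[seq_len(min(5L, length(v)))]) / sum(v)
  }, numeric(1))
  mito <- rep(NA_real_, ncol(m))
  rd <- if (is(x, "SummarizedExperiment")) SummarizedExperiment::rowData(x)
        else NULL
  if (!is.null(rd) && "is_mito" %in% colnames(rd)) {
    mt <- Matrix::colSums(m[rd$is_mito %in% TRUE, , drop = FALSE])
    mito <- ifelse(depth > 0, mt / depth, NA_real_)
  }
  S4Vectors::DataFrame(
    cell_id = colnames(m),
    depth = unname(depth),
    n_genes = unname(lengths(nz)),
    top5_fraction = unname(top5),
    mito_fraction = unname(mito),
    row.names = colnames(m))
}

#' Group-normalized QC metrics
#'
#' Cross-study QC needs metrics that are comparable between datasets with
#' very different depths and sensitivities. Each raw measurement is divided
#' by its median within the cell's (study, timepoint) group, so the metric is
#' interpreted relative to cells that shared the same biology and protocol.
#' By default the depth statistic is reported on a signed log2 scale
#' (`norm_depth = log2(depth / group median)`, so the cross-study cut of
#' -0.5 means "less than ~71% of the group-median depth") while the top-5
#' statistic stays a plain ratio (`norm_top5 = top5 / group median`, cut 1.3
#' meaning "30% above the group median"); both forms are configurable.
#'
#' @param qc `DataFrame` from [cellQCMetrics()].
#' @param metadata Per-cell metadata with `cell_id`, `study_id`,
#'   `timepoint_label` ([readCellMetadata()] or `colData`).
#' @param depth_scale `"log2_ratio"` (default) or `"ratio"`.
#' @param top5_scale `"ratio"` (default) or `"log2_ratio"`.
#' @return `qc` with added columns `study_id`, `timepoint_label`,
#'   `norm_depth`, `norm_top5`.
#' @export
normalizeQC <- function(qc, metadata,
                        depth_scale = c("log2_ratio", "ratio"),
                        top5_scale = c("ratio", "log2_ratio")) {
  depth_scale <- match.arg(depth_scale)
  top5_scale <- match.arg(top5_scale)
  md <- as.data.frame(metadata)
  idx <- match(qc$cell_id, md$cell_id)
  if (anyNA(idx))
    .stopf("cell '%s' absent from metadata", qc$cell_id[which(is.na(idx))[1]])
  qc$study_id <- md$study_id[idx]
  qc$timepoint_label <- md$timepoint_label[idx]
  grp <- paste(qc$study_id, qc$timepoint_label, sep = "\r")
  med_depth <- tapply(qc$depth, grp, median)
  med_top5 <- tapply(qc$top5_fraction, grp, median, na.rm = TRUE)
  if (any(med_depth == 0, na.rm = TRUE))
    .stopf("group '%s' has median depth 0; cannot normalize",
           names(med_depth)[which(med_depth == 0)[1]])
  if (any(med_top5 == 0, na.rm = TRUE))
    .stopf("a group has median top-5 fraction 0; cannot normalize")
  rd <- as.vector(qc$depth / med_depth[grp])
  rt <- as.vector(qc$top5_fraction / med_top5[grp])
  qc$norm_depth <- if (depth_scale == "log2_ratio") log2(rd) else rd
  qc$norm_top5 <- if (top5_scale == "log2_ratio") log2(rt) else rt
  qc
}

#' Apply the standardized cell filters
#'
#' Retains cells with `norm_depth >= depth_cut` (default -0.5) and
#' `norm_top5 <= top5_cut` (default 1.3; both boundaries inclusive) and
#' `n_genes > min_genes` (default 1000, strict). Cells with missing metrics
#' fail. The audit table records, per cell, which rule(s) removed it.
#'
#' @param qc `DataFrame` from [normalizeQC()].
#' @param depth_cut Lower cut on `norm_depth` (inclusive).
#' @param top5_cut Upper cut on `norm_top5` (inclusive).
#' @param min_genes Detected-genes threshold (strictly greater than).
#' @return A list: `retained` (character vector of cell ids) and `audit`
#'   (`DataFrame` with logical `fail_depth`, `fail_top5`, `fail_min_genes`,
#'   `retained`).
#' @export
filterCells <- function(qc, depth_cut = -0.5, top5_cut = 1.3,
                        min_genes = 1000) {
  need <- c("norm_depth", "norm_top5", "n_genes")
  miss <- setdiff(need, colnames(qc))
  if (length(miss))
    .stopf("qc lacks column(s) %s; run normalizeQC() first",
           paste(miss, collapse = ", "))
  fail_depth <- !(qc$norm_depth >= depth_cut) | is.na(qc$norm_depth)
  fail_top5 <- !(qc$norm_top5 <= top5_cut) | is.na(qc$norm_top5)
  fail_min_genes <- !(qc$n_genes > min_genes) | is.na(qc$n_genes)
  retained <- !(fail_depth | fail_top5 | fail_min_genes)
  audit <- S4Vectors::DataFrame(
    cell_id = qc$cell_id,
    fail_depth = fail_depth, fail_top5 = fail_top5,
    fail_min_genes = fail_min_genes, retained = retained,
    row.names = qc$cell_id)
  list(retained = qc$cell_id[retained], audit = audit)
}

#' Flag datasets with unusually high mitochondrial fractions
#'
#' Whole datasets whose cells carry an unusually high mitochondrial fraction
#' typically reflect harsh isolation (a chronic problem for adult
#' cardiomyocytes) and are excluded from cross-study analysis. The robust
#' default flags any dataset whose median cell mito fraction exceeds
#' `median + n_mad * MAD` of the per-dataset medians; a fixed threshold is
#' available as a simpler rule.
#'
#' @param qc `DataFrame` from [cellQCMetrics()] (needs `mito_fraction`).
#' @param metadata Per-cell metadata with `cell_id` and `study_id`.
#' @param rule `"mad"` (default) or `"fixed"`.
#' @param threshold Mito-fraction threshold for `rule = "fixed"`.
#' @param n_mad MAD multiplier for `rule = "mad"` (default 3).
#' @return `DataFrame`: `study_id`, `median_mito`, `n_cells`, `flagged`.
#' @export
datasetMitoFlag <- function(qc, metadata, rule = c("mad", "fixed"),
                            threshold = 0.5, n_mad = 3) {
  rule <- match.arg(rule)
  md <- as.data.frame(metadata)
  idx <- match(qc$cell_id, md$cell_id)
  study <- md$study_id[idx]
  meds <- tapply(qc$mito_fraction, study, median, na.rm = TRUE)
  n <- tapply(qc$cell_id, study, length)
  if (rule == "mad") {
    if (length(meds) < 2)
      .stopf("the MAD rule needs at least two datasets; use rule = 'fixed'")
    fence <- median(meds) + n_mad * mad(meds)
    flagged <- meds > fence
  } else {
    flagged <- meds > threshold
  }
  S4Vectors::DataFrame(study_id = names(meds),
                       median_mito = as.vector(meds),
                       n_cells = as.integer(as.vector(n)),
                       flagged = as.vector(flagged),
                       row.names = names(meds))
}

#' Entropy-score robustness to sequencing depth
#'
#' How far can a library be downsampled before the entropy score moves? For
#' each cell and each target depth, counts are subsampled without
#' replacement (multivariate hypergeometric — discarding reads from the
#' observed library) `n_reps` times and rescored. Per-cell accuracy at a
#' depth is `1 - |S_sub - S_base| / S_base`, averaged over replicates; the
#' curve reports the median across cells, plus the smallest tested depth
#' whose median accuracy reaches `accuracy_target` (default 0.98,
#' corresponding to roughly a 0.1 change on a score of 5 nats).
#'
#' Cells should satisfy the detected-genes QC (`n_genes > 1000`) at
#' baseline. Target depths above a cell's own depth skip that cell (with a
#' message); subsampling at exactly the cell's depth returns the baseline
#' score and accuracy 1.
#'
#' @param x An [EntropyExperiment-class] or genes x cells counts matrix.
#' @param target_depths Integer vector of depths to test.
#' @param n_reps Subsampling replicates per cell and depth.
#' @param k,log_base Scoring parameters (see [entropyScores()]).
#' @param accuracy_target Accuracy defining the minimal sufficient depth.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A list: `curve` (`DataFrame`: `target_depth`, `median_accuracy`,
#'   `mean_accuracy`, `n_cells`), `per_cell` (accuracy matrix, cells x
#'   depths), `min_depth_at_target` (smallest tested depth whose median
#'   accuracy is >= `accuracy_target`; `NA` if none).
#' @export
depthSubsamplingAccuracy <- function(x, target_depths, n_reps = 20,
                                     k = 1000, log_base = exp(1),
                                     accuracy_target = 0.98, seed = NULL) {
  m <- Matrix::drop0(methods::as(.countsOf(x), "CsparseMatrix"))
  target_depths <- sort(unique(as.integer(target_depths)))
  nz <- .perCellNonzero(m)
  depth <- vapply(nz, sum, numeric(1))
  base <- vapply(nz, function(v) .entropyAtK(v, k, log_base), numeric(1))
  acc <- matrix(NA_real_, nrow = ncol(m), ncol = length(target_depths),
                dimnames = list(colnames(m), as.character(target_depths)))
  .withSeed(seed, {
    for (j in seq_along(target_depths)) {
      d <- target_depths[j]
      for (i in seq_len(ncol(m))) {
        if (d > depth[i]) next
        if (d == depth[i]) { acc[i, j] <- 1; next }
        a <- vapply(seq_len(n_reps), function(r) {
          sub <- .subsampleCounts(nz[[i]], d)
          s <- .entropyAtK(sub[sub > 0], k, log_base)
          1 - abs(s - base[i]) / base[i]
        }, numeric(1))
        acc[i, j] <- mean(a)
      }
    }
  })
  skipped <- sum(is.na(acc))
  if (skipped)
    message(sprintf("%d cell/depth combination(s) skipped (target above cell depth)",
                    skipped))
  med <- apply(acc, 2, median, na.rm = TRUE)
  mn <- apply(acc, 2, mean, na.rm = TRUE)
  ncell <- apply(acc, 2, function(z) sum(!is.na(z)))
  ok <- which(med >= accuracy_target)
  list(curve = S4Vectors::DataFrame(target_depth = target_depths,
                                    median_accuracy = unname(med),
                                    mean_accuracy = unname(mn),
                                    n_cells = as.integer(unname(ncell))),
       per_cell = acc,
       min_depth_at_target = if (length(ok)) target_depths[min(ok)] else NA_integer_)
}
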