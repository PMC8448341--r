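#' Scan gene-subsampling levels K
#'
#' The choice of how many top genes to pool balances two failure modes: too
#' many genes re-introduces protocol-sensitivity differences; too few
#' compresses the dynamic range so that cells at different stages score
#' alike. The scan quantifies both. For each `k` in the grid, all cells are
#' scored at that `k`; medians are taken per (study, timepoint) group (or
#' per timepoint with `grouping = "timepoint"`); the scan reports
#' \itemize{
#'   \item `spearman_rho`: Spearman correlation between the group medians
#'     and `timepoint_rank` (maturation should push it toward -1);
#'   \item `norm_variance`: after min-max scaling the per-timepoint medians
#'     at each `k` to `[0, 1]`, their variance across timepoints (population
#'     convention) — larger means better stage separation.
#' }
#'
#' @param x Curated [EntropyExperiment-class] with cell metadata attached
#'   (or supply `metadata`).
#' @param k_grid Integer vector of subsampling levels.
#' @param metadata Optional per-cell metadata (`cell_id`, `study_id`,
#'   `timepoint_label`, `timepoint_rank`).
#' @param grouping `"study_timepoint"` (default, the correlation grouping)
#'   or `"timepoint"`.
#' @param log_base Logarithm base for scoring.
#' @return `DataFrame`: `k`, `spearman_rho`, `norm_variance`, `degenerate`
#'   (TRUE when the medians were constant and `norm_variance` is reported as
#'   0 by convention).
#' @seealso [selectK()] to pick `k` from the scan.
#' @export
geneSubsamplingScan <- function(x, k_grid, metadata = NULL,
                                grouping = c("study_timepoint", "timepoint"),
                                log_base = exp(1)) {
  grouping <- match.arg(grouping)
  md <- .cellMeta(x, metadata)
  need <- c("study_id", "timepoint_label", "timepoint_rank")
  miss <- setdiff(need, colnames(md))
  if (length(miss))
    .stopf("metadata lacks column(s): %s", paste(miss, collapse = ", "))
  if (length(unique(md$timepoint_label)) < 2)
    .stopf("at least two distinct timepoints are required")
  m <- Matrix::drop0(methods::as(.countsOf(x), "CsparseMatrix"))
  nz <- .perCellNonzero(m)
  k_grid <- sort(unique(as.integer(k_grid)))
  ## scores for all k at once from each cell's sorted prefix sums
  smat <- vapply(nz, function(v) .entropyAtK(v, k_grid, log_base),
                 numeric(length(k_grid)))
  smat <- if (length(k_grid) == 1L) matrix(smat, ncol = 1L) else t(smat)
  colnames(smat) <- as.character(k_grid)
  grp <- if (grouping == "study_timepoint")
    paste(md$study_id, md$timepoint_label, sep = "\r") else md$timepoint_label
  rank_of_grp <- tapply(md$timepoint_rank, grp, function(z) z[1])
  tp_of_cell <- md$timepoint_label
  out <- lapply(seq_along(k_grid), function(j) {
    med_grp <- tapply(smat[, j], grp, median)
    rho <- suppressWarnings(
      cor(med_grp, rank_of_grp[names(med_grp)], method = "spearman"))
    med_tp <- tapply(smat[, j], tp_of_cell, median)
    rng <- range(med_tp)
    degen <- diff(rng) == 0
    nv <- if (degen) 0 else .popVar((med_tp - rng[1]) / diff(rng))
    c(rho = rho, nv = nv, degen = as.numeric(degen))
  })
  out <- do.call(rbind, out)
  S4Vectors::DataFrame(k = k_grid,
                       spearman_rho = unname(out[, "rho"]),
                       norm_variance = unname(out[, "nv"]),
                       degenerate = unname(out[, "degen"] == 1))
}

.cellMeta <- function(x, metadata) {
  if (!is.null(metadata)) return(as.data.frame(metadata))
  if (is(x, "SummarizedExperiment")) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    if (!"cell_id" %in% colnames(cd)) cd$cell_id <- colnames(x)
    return(cd)
  }
  .stopf("per-cell metadata required")
}

#' Select the gene-subsampling level K
#'
#' Picks the `k` that is jointly within tolerance of the best `|rho|` and
#' the best normalized variance over the scan grid. Ties are broken toward
#' 1000 (the cross-study default), then toward the smaller `k`. If no `k`
#' satisfies both tolerances the `|rho|`-argmax is returned with a warning.
#'
#' @param scan `DataFrame` from [geneSubsamplingScan()].
#' @param rho_tolerance Allowed shortfall from the best `|spearman_rho|`.
#' @param var_tolerance Allowed shortfall from the best `norm_variance`.
#' @return A list: `k` (chosen level) and `table` (the scan annotated with
#'   logical columns `ok_rho`, `ok_var`, `admissible`).
#' @export
selectK <- function(scan, rho_tolerance = 0.05, var_tolerance = 0.05) {
  if (!nrow(scan)) .stopf("empty scan")
  eps <- sqrt(.Machine$double.eps)
  arho <- abs(scan$spearman_rho)
  ok_rho <- arho >= max(arho, na.rm = TRUE) - rho_tolerance - eps
  best_var <- max(scan$norm_variance, na.rm = TRUE)
  ok_var <- scan$norm_variance >= best_var - var_tolerance - eps
  admissible <- ok_rho & ok_var & !is.na(arho)
  tab <- scan
  tab$ok_rho <- ok_rho
  tab$ok_var <- ok_var
  tab$admissible <- admissible
  if (!any(admissible)) {
    .warnf("no k satisfies both tolerances; returning the |rho|-argmax")
    cand <- which(arho == max(arho, na.rm = TRUE))
  } else {
    cand <- which(admissible)
  }
  ## toward 1000, then toward smaller k
  d <- abs(scan$k[cand] - 1000)
  cand <- cand[d == min(d)]
  k <- min(scan$k[cand])
  list(k = as.integer(k), table = tab)
}

#' Pre- vs post-UMI-collapse score concordance
#'
#' Entropy scores should barely move when read counts are collapsed to
#' molecule (UMI) counts, because the score is invariant to uniform
#' amplification and the top-k pool is dominated by high-count genes. This
#' check scores the same cells from both matrices and reports the per-cell
#' ratio `score(reads) / score(umi)` with per-dataset summaries.
#'
#' @param reads [EntropyExperiment-class] with `datatype == "reads"`.
#' @param umi [EntropyExperiment-class] with `datatype == "umi"`, same cells
#'   and same (curated) gene universe.
#' @param k,log_base Scoring parameters.
#' @param metadata Optional per-cell metadata providing `study_id` for the
#'   per-dataset summary; defaults to `colData(umi)` when present.
#' @return A list: `per_cell` (`DataFrame`: `cell_id`, `score_reads`,
#'   `score_umi`, `ratio`) and `summary` (`DataFrame` per dataset:
#'   `study_id`, `mean_ratio`, `sd_ratio`, `n_cells`).
#' @export
umiCollapseRatio <- function(reads, umi, k = 1000, log_base = exp(1),
                             metadata = NULL) {
  cr <- colnames(reads)
  cu <- colnames(umi)
  if (!setequal(cr, cu) || length(cr) != length(cu)) {
    d1 <- setdiff(cr, cu); d2 <- setdiff(cu, cr)
    .stopf("cell sets differ: %d only in reads (e.g. %s), %d only in umi (e.g. %s)",
           length(d1), if (length(d1)) d1[1] else "-",
           length(d2), if (length(d2)) d2[1] else "-")
  }
  if (!setequal(rownames(reads), rownames(umi)))
    .stopf("gene universes differ between the reads and umi matrices")
  sr <- entropyScores(reads, k = k, log_base = log_base)
  su <- entropyScores(umi, k = k, log_base = log_base)
  su <- su[sr$cell_id, ]
  per_cell <- S4Vectors::DataFrame(
    cell_id = sr$cell_id,
    score_reads = sr$score,
    score_umi = su$score,
    ratio = sr$score / su$score,
    row.names = sr$cell_id)
  md <- tryCatch(.cellMeta(umi, metadata), error = function(e) NULL)
  study <- if (!is.null(md) && "study_id" %in% colnames(md))
    md$study_id[match(per_cell$cell_id, md$cell_id)] else "all"
  mean_r <- tapply(per_cell$ratio, study, mean)
  sd_r <- tapply(per_cell$ratio, study, stats::sd)
  n <- tapply(per_cell$ratio, study, length)
  list(per_cell = per_cell,
       summary = S4Vectors::DataFrame(study_id = names(mean_r),
                                      mean_ratio = as.vector(mean_r),
                                      sd_ratio = as.vector(sd_r),
                                      n_cells = as.integer(as.vector(n)),
                                      row.names = names(mean_r)))
}
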