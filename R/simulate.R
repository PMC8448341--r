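#' Specification for the synthetic maturation series
#'
#' The generator emulates the statistical structure the entropy score relies
#' on: cells transition from a broad gene distribution (high entropy) to a
#' narrow one (low entropy) as they mature. Per stage, gene probabilities
#' follow a Zipf (power-law) profile over a fixed gene ranking,
#' `P(rank) ~ rank^-s`, with the exponent `s` increasing linearly across
#' stages so later stages concentrate mass on fewer genes. On top of the
#' nuclear profile the generator layers stage-graded mitochondrial mass,
#' protocol-specific ribosomal-protein mass, pseudogene mismapping of
#' mitochondrial counts (a fraction `pseudogene_mismap_fraction` of each
#' mitochondrial gene's counts is emitted under a paired NUMT pseudogene
#' id), damaged cells (depth collapsed to 10%, or one gene boosted to 60% of
#' depth), and finite protocol sensitivity (detection truncated to the top
#' `sensitivity` genes per cell).
#'
#' Defaults describe a mid-sized six-stage series: 200 cells/stage, 8000
#' genes, Zipf exponent 0.6 to 1.4, log-normal depths with median 10000.
#'
#' @param n_stages Number of maturation stages.
#' @param cells_per_stage Cells per stage.
#' @param n_genes Total genes, including 13 mitochondrial genes, their 13
#'   paired pseudogenes, and 80 ribosomal-protein genes.
#' @param zipf_range `c(s_min, s_max)`; exponent increases linearly with
#'   stage. Requires `s_min < s_max`.
#' @param depth_meanlog,depth_sdlog Log-normal depth parameters (default
#'   median `exp(depth_meanlog) = 10000`).
#' @param sensitivity Detected-genes ceiling per cell (`Inf` = no ceiling).
#' @param mito_fraction_by_stage Per-stage mitochondrial mass (recycled to
#'   `n_stages`); defaults ramp 0.05 to 0.30, mirroring the rise of
#'   mitochondrial content with cardiomyocyte maturation.
#' @param ribosomal_fraction Ribosomal-protein mass for the simulated
#'   protocol (scalar).
#' @param pseudogene_mismap_fraction Fraction of mitochondrial counts
#'   emitted under pseudogene ids (0 = clean mapping).
#' @param damaged_cell_fraction Fraction of cells injected as damaged.
#' @param read_duplication_mean Mean reads per molecule used by
#'   [simulateUMIDuplication()].
#' @param seed Integer seed; every generator draw is reproducible from it.
#' @return A validated `SyntheticSpec` (list).
#' @export
syntheticSpec <- function(n_stages = 6L, cells_per_stage = 200L,
                          n_genes = 8000L, zipf_range = c(0.6, 1.4),
                          depth_meanlog = log(10000), depth_sdlog = 0.3,
                          sensitivity = Inf,
                          mito_fraction_by_stage = NULL,
                          ribosomal_fraction = 0.10,
                          pseudogene_mismap_fraction = 0.25,
                          damaged_cell_fraction = 0.05,
                          read_duplication_mean = 4,
                          seed = 1L) {
  if (is.null(mito_fraction_by_stage))
    mito_fraction_by_stage <- seq(0.05, 0.30, length.out = n_stages)
  mito_fraction_by_stage <- rep_len(mito_fraction_by_stage, n_stages)
  spec <- list(n_stages = as.integer(n_stages),
               cells_per_stage = as.integer(cells_per_stage),
               n_genes = as.integer(n_genes),
               zipf_range = zipf_range,
               depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
               sensitivity = sensitivity,
               mito_fraction_by_stage = mito_fraction_by_stage,
               ribosomal_fraction = ribosomal_fraction,
               pseudogene_mismap_fraction = pseudogene_mismap_fraction,
               damaged_cell_fraction = damaged_cell_fraction,
               read_duplication_mean = read_duplication_mean,
               seed = as.integer(seed))
  .validateSpec(spec)
  class(spec) <- c("SyntheticSpec", "list")
  spec
}

.validateSpec <- function(s) {
  if (s$n_stages < 1 || s$cells_per_stage < 1) .stopf("stage/cell counts must be positive")
  if (length(s$zipf_range) != 2 || s$zipf_range[1] >= s$zipf_range[2])
    .stopf("zipf_range must be c(s_min, s_max) with s_min < s_max")
  fr <- c(s$mito_fraction_by_stage, s$ribosomal_fraction,
          s$pseudogene_mismap_fraction, s$damaged_cell_fraction)
  if (any(fr < 0 | fr > 1)) .stopf("all fractions must lie in [0, 1]")
  if (any(s$mito_fraction_by_stage + s$ribosomal_fraction >= 1))
    .stopf("mito + ribosomal mass must stay below 1 at every stage")
  if (s$n_genes < 200) .stopf("n_genes must be at least 200")
  if (s$read_duplication_mean < 1) .stopf("read_duplication_mean must be >= 1")
  invisible(TRUE)
}

## Fixed gene universe for a spec: 13 mito genes + 13 paired pseudogenes +
## 80 ribosomal-protein genes + nuclear background.
.syntheticGenes <- function(spec) {
  mito_sym <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8", "mt-Atp6",
                "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4", "mt-Nd5", "mt-Nd6",
                "mt-Cytb")
  pseudo_sym <- paste0("Gm-", sub("^mt-", "mt", mito_sym), "-ps")
  ribo_sym <- c(paste0("Rps", 1:40), paste0("Rpl", 1:40))
  n_bg <- spec$n_genes - length(mito_sym) - length(pseudo_sym) - length(ribo_sym)
  bg_sym <- sprintf("Gene%05d", seq_len(n_bg))
  bg_bt <- rep("protein_coding", n_bg)
  ## a sprinkling of non-coding background, all within the default keep-set
  bg_bt[seq_len(n_bg) %% 20 == 0] <- "lncRNA"
  bg_bt[seq_len(n_bg) %% 20 == 10] <- "antisense"
  data.frame(
    gene_id = c(mito_sym, pseudo_sym, ribo_sym, bg_sym),
    gene_symbol = c(mito_sym, pseudo_sym, ribo_sym, bg_sym),
    biotype = c(rep("protein_coding", length(mito_sym)),
                rep("pseudogene", length(pseudo_sym)),
                rep("protein_coding", length(ribo_sym)),
                bg_bt),
    chromosome = c(rep("MT", length(mito_sym)),
                   rep("1", length(pseudo_sym)),
                   rep("2", length(ribo_sym)),
                   rep("3", n_bg)),
    class = c(rep("mito", length(mito_sym)), rep("pseudo", length(pseudo_sym)),
              rep("ribo", length(ribo_sym)), rep("bg", n_bg)),
    stringsAsFactors = FALSE)
}

#' Gene annotation table for generated data
#'
#' The per-gene annotation matching [simulateMaturationSeries()] output,
#' in the [readGeneTable()] column layout.
#'
#' @param spec A `SyntheticSpec`.
#' @return A `DataFrame` usable with [annotateGenes()] and the curation
#'   functions.
#' @export
syntheticGeneTable <- function(spec) {
  g <- .syntheticGenes(spec)
  parent <- rep(NA_character_, nrow(g))
  parent[g$class == "pseudo"] <- g$gene_id[g$class == "mito"]
  S4Vectors::DataFrame(
    gene_id = g$gene_id, gene_symbol = g$gene_symbol, biotype = g$biotype,
    chromosome = g$chromosome, is_mito = .isMitoChrom(g$chromosome),
    is_ribosomal_protein = grepl("^Rp[sl]", g$gene_symbol),
    pseudogene_parent = parent)
}

#' Pseudogene map of the generator
#'
#' The pairing used when `pseudogene_mismap_fraction > 0`:
#' each synthetic NUMT pseudogene maps back to the mitochondrial gene whose
#' counts it siphons. Feeding this to [correctPseudogenes()] inverts the
#' generator's mismapping exactly.
#'
#' @param spec A `SyntheticSpec`.
#' @return Named character vector (pseudogene id -> mito gene id).
#' @export
syntheticPseudogeneMap <- function(spec) {
  g <- .syntheticGenes(spec)
  setNames(g$gene_id[g$class == "mito"], g$gene_id[g$class == "pseudo"])
}

#' Simulate a maturation series
#'
#' Generates the full synthetic study: per stage, a Zipf gene profile whose
#' exponent increases with stage (narrowing the distribution), blended with
#' stage-specific mitochondrial mass and protocol ribosomal mass; per cell,
#' a log-normal depth and multinomial counts; then optional detection
#' truncation, pseudogene mismapping, and damaged-cell injection. All
#' randomness derives from `spec$seed` and outputs are bit-reproducible.
#'
#' @param spec A `SyntheticSpec` from [syntheticSpec()].
#' @param study_id,protocol Labels recorded in the metadata.
#' @return A list: `experiment` ([EntropyExperiment-class] with gene
#'   annotation and cell metadata attached), `metadata` (per-cell
#'   `DataFrame`), `truth` (per-cell `DataFrame`: `cell_id`, `stage`,
#'   `timepoint_rank`, `zipf_exponent`, `damaged`, `damage_type`,
#'   `true_mito_counts`), `gene_table`, `pseudogene_map`.
#' @export
simulateMaturationSeries <- function(spec, study_id = "synthetic-1",
                                     protocol = "synthetic") {
  .validateSpec(spec)
  genes <- .syntheticGenes(spec)
  .withSeed(spec$seed, .simulateSeries(spec, genes, study_id, protocol))
}

.simulateSeries <- function(spec, genes, study_id, protocol) {
  idx_mito <- which(genes$class == "mito")
  idx_pseudo <- which(genes$class == "pseudo")
  idx_ribo <- which(genes$class == "ribo")
  idx_bg <- which(genes$class == "bg")
  s_grid <- seq(spec$zipf_range[1], spec$zipf_range[2],
                length.out = spec$n_stages)
  ## fixed gene ranking shared by all stages: the generator's "identity" of
  ## which genes are most expressed does not change with maturation, only
  ## how concentrated the distribution is
  n_cells <- spec$n_stages * spec$cells_per_stage
  counts <- vector("list", n_cells)
  stage_of <- integer(n_cells)
  mito_profile <- (seq_along(idx_mito))^-1
  mito_profile <- mito_profile / sum(mito_profile)
  ribo_profile <- (seq_along(idx_ribo))^-0.5
  ribo_profile <- ribo_profile / sum(ribo_profile)
  cell <- 0L
  for (t in seq_len(spec$n_stages)) {
    bg_profile <- (seq_along(idx_bg))^-s_grid[t]
    bg_profile <- bg_profile / sum(bg_profile)
    m <- spec$mito_fraction_by_stage[t]
    r <- spec$ribosomal_fraction
    p <- numeric(nrow(genes))
    p[idx_bg] <- (1 - m - r) * bg_profile
    p[idx_mito] <- m * mito_profile
    p[idx_ribo] <- r * ribo_profile
    for (j in seq_len(spec$cells_per_stage)) {
      cell <- cell + 1L
      depth <- max(50L, round(rlnorm(1, spec$depth_meanlog, spec$depth_sdlog)))
      counts[[cell]] <- rmultinom(1, depth, p)[, 1]
      stage_of[cell] <- t
    }
  }
  cm <- do.call(cbind, counts)
  rownames(cm) <- genes$gene_id
  colnames(cm) <- sprintf("cell%04d", seq_len(n_cells))
  ## finite protocol sensitivity: only the top `sensitivity` genes per cell
  ## are detected
  if (is.finite(spec$sensitivity) && spec$sensitivity < nrow(cm))
    cm <- .truncateSensitivity(cm, spec$sensitivity)
  ## damaged cells: half collapse to 10% depth, half dominated by one gene
  damaged <- rep(FALSE, n_cells)
  damage_type <- rep("", n_cells)
  n_dam <- round(spec$damaged_cell_fraction * n_cells)
  if (n_dam > 0) {
    which_dam <- sample.int(n_cells, n_dam)
    damaged[which_dam] <- TRUE
    for (i in seq_along(which_dam)) {
      ci <- which_dam[i]
      v <- cm[, ci]
      if (i %% 2 == 1) {
        damage_type[ci] <- "low_depth"
        cm[, ci] <- .subsampleCounts(v, max(1L, round(0.1 * sum(v))))
      } else {
        damage_type[ci] <- "dominated"
        top <- which.max(v)
        others <- sum(v) - v[top]
        v[top] <- round(1.5 * others)  # 60% of the new depth
        cm[, ci] <- v
      }
    }
  }
  true_mito <- Matrix::colSums(cm[idx_mito, , drop = FALSE])
  ## pseudogene mismapping: each mito count lands on the paired NUMT with
  ## probability phi
  if (spec$pseudogene_mismap_fraction > 0) {
    phi <- spec$pseudogene_mismap_fraction
    for (g in seq_along(idx_mito)) {
      v <- cm[idx_mito[g], ]
      moved <- rbinom(n_cells, v, phi)
      cm[idx_mito[g], ] <- v - moved
      cm[idx_pseudo[g], ] <- cm[idx_pseudo[g], ] + moved
    }
  }
  md <- S4Vectors::DataFrame(
    cell_id = colnames(cm),
    study_id = study_id,
    timepoint_label = sprintf("stage%02d", stage_of),
    timepoint_rank = stage_of,
    species = "synthetic",
    protocol = protocol,
    datatype = "umi",
    row.names = colnames(cm))
  truth <- S4Vectors::DataFrame(
    cell_id = colnames(cm),
    stage = sprintf("stage%02d", stage_of),
    timepoint_rank = stage_of,
    zipf_exponent = s_grid[stage_of],
    damaged = damaged,
    damage_type = damage_type,
    true_mito_counts = unname(true_mito),
    row.names = colnames(cm))
  gt <- syntheticGeneTable(spec)
  ee <- EntropyExperiment(methods::as(cm, "CsparseMatrix"), geneData = gt,
                          cellData = md, datatype = "umi")
  list(experiment = ee, metadata = md, truth = truth, gene_table = gt,
       pseudogene_map = syntheticPseudogeneMap(spec))
}

## Zero all but each cell's `g` highest-count genes (ties: first index kept),
## modelling a detection ceiling.
.truncateSensitivity <- function(cm, g) {
  for (j in seq_len(ncol(cm))) {
    v <- cm[, j]
    ndet <- sum(v > 0)
    if (ndet <= g) next
    keep <- order(v, decreasing = TRUE)[seq_len(g)]
    w <- numeric(length(v))
    w[keep] <- v[keep]
    cm[, j] <- w
  }
  cm
}

#' Simulate read-level PCR duplication of a UMI matrix
#'
#' Each molecule is amplified into `1 + Geometric` reads with the stated
#' mean, so summing reads per gene and cell gives a pre-collapse reads
#' matrix; collapsing the duplicates reproduces the UMI matrix exactly by
#' construction. Used to probe the score's robustness to amplification
#' (see [umiCollapseRatio()]).
#'
#' @param umi An [EntropyExperiment-class] with `datatype == "umi"`.
#' @param read_duplication_mean Mean reads per molecule (>= 1; 1 means no
#'   duplication and returns the counts unchanged).
#' @param seed Integer seed.
#' @return An [EntropyExperiment-class] with `datatype == "reads"`.
#' @export
simulateUMIDuplication <- function(umi, read_duplication_mean = 4, seed = 1L) {
  if (read_duplication_mean < 1)
    .stopf("read_duplication_mean must be >= 1")
  if (!identical(datatype(umi), "umi"))
    .stopf("input datatype must be 'umi'")
  m <- Matrix::drop0(methods::as(.countsOf(umi), "CsparseMatrix"))
  out <- umi
  if (read_duplication_mean > 1) {
    ## n molecules, each 1 + Geom(p): total = n + NegBinomial(n, p),
    ## p = 1 / mean
    p <- 1 / read_duplication_mean
    x <- m@x
    m@x <- .withSeed(seed, x + rnbinom(length(x), size = x, prob = p))
  }
  SummarizedExperiment::assay(out, "counts") <- m
  datatype(out) <- "reads"
  out
}

#' Simulate a protocol-sensitivity pair
#'
#' Two matrices over the same cells and the same underlying per-stage
#' distributions, differing only in how many genes each "protocol" detects
#' per cell — the situation top-K subsetting is designed to standardize.
#' One base series is drawn (without a detection ceiling) and then truncated
#' at each sensitivity, so the pair is matched cell for cell.
#'
#' @param spec A `SyntheticSpec`.
#' @param sensitivities `c(g1, g2)` with `g1 < g2 <= n_genes`.
#' @return A list: `low`, `high` (the two [EntropyExperiment-class]
#'   objects, low/high sensitivity), `metadata`, `truth`, `gene_table`,
#'   `pseudogene_map`.
#' @export
simulateSensitivityPair <- function(spec, sensitivities = c(3000, 7000)) {
  if (length(sensitivities) != 2 || sensitivities[1] >= sensitivities[2])
    .stopf("sensitivities must be c(g1, g2) with g1 < g2")
  if (sensitivities[2] > spec$n_genes)
    .stopf("sensitivity exceeds n_genes")
  base_spec <- spec
  base_spec$sensitivity <- Inf
  sim <- simulateMaturationSeries(base_spec, study_id = "sensitivity-pair")
  cm <- .countsOf(sim$experiment)
  dense <- as.matrix(cm)
  mk <- function(g, label) {
    tm <- .truncateSensitivity(dense, g)
    md <- sim$metadata
    md$protocol <- label
    md$study_id <- label
    EntropyExperiment(methods::as(tm, "CsparseMatrix"),
                      geneData = sim$gene_table, cellData = md,
                      datatype = "umi")
  }
  list(low = mk(sensitivities[1], "protocol-low"),
       high = mk(sensitivities[2], "protocol-high"),
       metadata = sim$metadata, truth = sim$truth,
       gene_table = sim$gene_table, pseudogene_map = sim$pseudogene_map)
}
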