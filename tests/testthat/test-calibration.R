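test_that("scanning at k = total genes reproduces unsubsetted entropy", {
  sim <- smallSeries(seed = 41, cells_per_stage = 6, n_genes = 400)
  ee <- sim$experiment
  scan <- geneSubsamplingScan(ee, k_grid = nrow(ee))
  sc_full <- entropyScores(ee, k = nrow(ee))
  oracle <- vapply(seq_len(ncol(ee)), function(j) {
    v <- .counts(ee)[, j]
    shannonEntropy(geneProbabilities(v))
  }, numeric(1))
  expect_equal(sc_full$score, oracle, tolerance = 1e-12)
  expect_true(is.finite(scan$spearman_rho))
})

test_that("perfectly monotone medians give rho = -1", {
  sim <- smallSeries(seed = 43, cells_per_stage = 15, n_genes = 1200,
                     damaged_cell_fraction = 0)
  scan <- geneSubsamplingScan(sim$experiment, k_grid = c(250, 1000))
  expect_equal(unname(scan$spearman_rho), c(-1, -1))
})

test_that("normalized variance follows the min-max population convention", {
  ## three timepoints with medians [6, 5, 3] -> scaled [1, 2/3, 0],
  ## population variance 14/81
  x <- c(1, 2/3, 0)
  expect_equal(mean((x - mean(x))^2), 14 / 81)
  ## one uniform-ish cell per timepoint, constructed so per-timepoint median
  ## entropies are distinct; the scan must min-max scale them before the
  ## variance
  cells <- list(
    c1 = setNames(rep(4, 400), sprintf("g%04d", 1:400)),
    c2 = setNames(rep(4, 40), sprintf("g%04d", 1:40)),
    c3 = setNames(rep(4, 8), sprintf("g%04d", 1:8)))
  ee <- toyExperiment(cells)
  md <- toyMetadata(names(cells), timepoint = c("t1", "t2", "t3"),
                    rank = 1:3)
  ee <- annotateCells(ee, md)
  scan <- geneSubsamplingScan(ee, k_grid = 1000)
  meds <- log(c(400, 40, 8))
  scaled <- (meds - min(meds)) / diff(range(meds))
  expect_equal(scan$norm_variance, mean((scaled - mean(scaled))^2),
               tolerance = 1e-12)
  expect_false(scan$degenerate)
})

test_that("constant medians are degenerate with variance 0 by convention", {
  cells <- list(c1 = setNames(rep(2, 50), paste0("g", 1:50)),
                c2 = setNames(rep(3, 50), paste0("g", 1:50)))
  ee <- toyExperiment(cells)
  ee <- annotateCells(ee, toyMetadata(names(cells),
                                      timepoint = c("t1", "t2"), rank = 1:2))
  scan <- geneSubsamplingScan(ee, k_grid = 100)
  expect_true(scan$degenerate)
  expect_equal(scan$norm_variance, 0)
})

test_that("a single timepoint is an error", {
  sim <- smallSeries(seed = 47, cells_per_stage = 4, n_genes = 300,
                     n_stages = 2)
  ee <- sim$experiment
  ee1 <- ee[, sim$metadata$timepoint_rank == 1]
  expect_error(geneSubsamplingScan(ee1, k_grid = 100), "two distinct timepoints")
})

test_that("selectK picks the joint-tolerance winner with ties toward 1000", {
  scan <- S4Vectors::DataFrame(
    k = c(250L, 500L, 1000L, 2000L),
    spearman_rho = c(-0.90, -0.97, -0.96, -0.98),
    norm_variance = c(0.20, 0.19, 0.18, 0.10),
    degenerate = FALSE)
  ## tolerances admit k in {500, 1000, 2000} by rho and {250, 500, 1000} by
  ## variance; intersection {500, 1000}; tie broken toward 1000
  sel <- selectK(scan, rho_tolerance = 0.02, var_tolerance = 0.02)
  expect_identical(sel$k, 1000L)
  ## brute-force Pareto enumeration agrees with the admissible column
  ## (tolerance boundaries are inclusive, hence the epsilon)
  arho <- abs(scan$spearman_rho)
  adm <- arho >= max(arho) - 0.02 - 1e-9 &
    scan$norm_variance >= max(scan$norm_variance) - 0.02 - 1e-9
  expect_identical(unname(sel$table$admissible), unname(adm))
  ## one dominating k wins outright
  sel2 <- selectK(scan, rho_tolerance = 0.005, var_tolerance = 0.2)
  expect_identical(sel2$k, 2000L)
  ## all-equivalent grid falls back to the point nearest 1000
  scan3 <- S4Vectors::DataFrame(k = c(400L, 800L, 1500L),
                                spearman_rho = -0.95,
                                norm_variance = 0.15, degenerate = FALSE)
  expect_identical(selectK(scan3, 0.1, 0.1)$k, 800L)
  ## empty joint set warns and returns the |rho| argmax
  expect_warning(sel4 <- selectK(scan, rho_tolerance = 0, var_tolerance = 0),
                 "no k satisfies")
  expect_identical(sel4$k, 2000L)
})

test_that("selectK is invariant to the order of the scan rows", {
  scan <- S4Vectors::DataFrame(
    k = c(250L, 500L, 1000L, 2000L),
    spearman_rho = c(-0.90, -0.97, -0.96, -0.98),
    norm_variance = c(0.20, 0.19, 0.18, 0.10), degenerate = FALSE)
  perm <- scan[c(3, 1, 4, 2), ]
  expect_identical(selectK(scan, 0.02, 0.02)$k, selectK(perm, 0.02, 0.02)$k)
})

test_that("identical read/UMI matrices give ratio exactly 1", {
  sim <- smallSeries(seed = 53, cells_per_stage = 5, n_genes = 400)
  umi <- sim$experiment
  reads <- umi
  datatype(reads) <- "reads"
  res <- umiCollapseRatio(reads, umi, k = 200)
  expect_true(all(res$per_cell$ratio == 1))
  expect_equal(unname(res$summary$mean_ratio), 1)
})

test_that("uniform duplication leaves the ratio exactly 1 (scale invariance)", {
  sim <- smallSeries(seed = 59, cells_per_stage = 5, n_genes = 400)
  umi <- sim$experiment
  reads <- umi
  SummarizedExperiment::assay(reads, "counts") <- .counts(umi) * 3
  datatype(reads) <- "reads"
  res <- umiCollapseRatio(reads, umi, k = 200)
  expect_true(all(res$per_cell$ratio == 1))
})

test_that("mismatched cell sets are reported with the symmetric difference", {
  sim <- smallSeries(seed = 61, cells_per_stage = 3, n_genes = 300)
  umi <- sim$experiment
  reads <- umi[, -1]
  datatype(reads) <- "reads"
  expect_error(umiCollapseRatio(reads, umi), "cell sets differ")
})
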