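test_that("per-cell QC metrics match enumeration", {
  ee <- toyExperiment(list(
    c1 = setNames(c(50, 20, 10, 10, 5, 5), paste0("g", 1:6)),
    c2 = c(g1 = 4, g2 = 3, g3 = 3),
    c3 = c("mt-Nd1" = 30, g1 = 70)))
  qc <- cellQCMetrics(ee)
  expect_equal(qc["c1", "depth"], 100)
  expect_equal(qc["c1", "n_genes"], 6)
  expect_equal(qc["c1", "top5_fraction"], 0.95)
  ## <= 5 detected genes: top-5 fraction is 1 by definition
  expect_equal(qc["c2", "top5_fraction"], 1)
  expect_equal(qc["c3", "mito_fraction"], 0.3)
})

test_that("zero-depth cells keep a row with missing fractions and fail filters", {
  m <- cbind(toyMatrix(list(c1 = c(g1 = 10, g2 = 10))), c0 = 0)
  ee <- EntropyExperiment(m, geneData = toyGeneTable(rownames(m)))
  qc <- cellQCMetrics(ee)
  expect_true("c0" %in% qc$cell_id)
  expect_true(is.na(qc["c0", "top5_fraction"]))
  qc <- normalizeQC(qc, toyMetadata(qc$cell_id))
  flt <- filterCells(qc, min_genes = 1)
  expect_false("c0" %in% flt$retained)
})

test_that("group normalization gives the documented closed forms", {
  qc <- S4Vectors::DataFrame(
    cell_id = paste0("c", 1:3), depth = c(1000, 2000, 4000),
    n_genes = rep(2000L, 3), top5_fraction = c(0.4, 0.5, 0.65),
    mito_fraction = 0.1)
  out <- normalizeQC(qc, toyMetadata(qc$cell_id))
  expect_equal(out$norm_depth, c(-1, 0, 1))
  expect_equal(out$norm_top5, c(0.8, 1.0, 1.3))
  ## singleton group normalizes to its own median
  out1 <- normalizeQC(qc[1, ], toyMetadata("c1"))
  expect_equal(out1$norm_depth, 0)
  expect_equal(out1$norm_top5, 1)
})

test_that("normalization is equivariant to scaling all depths in a group", {
  set.seed(2)
  qc <- S4Vectors::DataFrame(
    cell_id = paste0("c", 1:20), depth = sample(500:5000, 20),
    n_genes = 1500L, top5_fraction = runif(20, 0.2, 0.6),
    mito_fraction = 0.1)
  md <- toyMetadata(qc$cell_id)
  a <- normalizeQC(qc, md)
  qc2 <- qc
  qc2$depth <- qc2$depth * 17
  b <- normalizeQC(qc2, md)
  expect_equal(a$norm_depth, b$norm_depth)
})

test_that("cell filters use the stated boundary conventions", {
  qc <- S4Vectors::DataFrame(
    cell_id = paste0("c", 1:3), depth = c(1000, 2000, 4000),
    n_genes = c(1500L, 1000L, 1500L), top5_fraction = c(0.4, 0.5, 0.65),
    mito_fraction = 0.1)
  out <- normalizeQC(qc, toyMetadata(qc$cell_id))
  flt <- filterCells(out, depth_cut = -0.5, top5_cut = 1.3, min_genes = 999)
  ## norm_depth [-1, 0, 1]: only the first cell fails the depth cut
  expect_identical(unname(flt$audit$fail_depth), c(TRUE, FALSE, FALSE))
  ## norm_top5 1.3 exactly is retained (inclusive)
  expect_identical(unname(flt$audit$fail_top5), c(FALSE, FALSE, FALSE))
  expect_identical(flt$retained, c("c2", "c3"))
  ## n_genes == min_genes is removed (strict >)
  flt2 <- filterCells(out, min_genes = 1000)
  expect_true(flt2$audit["c2", "fail_min_genes"])
  ## audit partitions the cells
  expect_identical(sort(c(flt$retained,
                          flt$audit$cell_id[!flt$audit$retained])),
                   sort(qc$cell_id))
})

test_that("dataset mito flagging applies the MAD fence and fixed rules", {
  qc <- S4Vectors::DataFrame(
    cell_id = paste0("c", 1:8),
    depth = 1000, n_genes = 1200L, top5_fraction = 0.3,
    mito_fraction = rep(c(0.2, 0.25, 0.3, 0.8), each = 2))
  md <- toyMetadata(qc$cell_id, study = rep(paste0("d", 1:4), each = 2))
  out <- datasetMitoFlag(qc, md, rule = "mad")
  ## oracle fence: median + 3 * 1.4826 * median absolute deviation
  meds <- c(0.2, 0.25, 0.3, 0.8)
  fence <- median(meds) + 3 * 1.4826 * median(abs(meds - median(meds)))
  expect_identical(unname(out$flagged), meds > fence)
  expect_identical(unname(out$flagged), c(FALSE, FALSE, FALSE, TRUE))
  ## identical datasets: nothing flagged
  qc2 <- qc; qc2$mito_fraction <- 0.25
  expect_false(any(datasetMitoFlag(qc2, md, rule = "mad")$flagged))
  out3 <- datasetMitoFlag(qc, md, rule = "fixed", threshold = 0.5)
  expect_identical(unname(out3$flagged), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("subsampling at a cell's own depth returns accuracy exactly 1", {
  sim <- smallSeries(seed = 23, cells_per_stage = 4, n_genes = 500)
  ee <- sim$experiment
  d <- min(depths(ee))
  res <- depthSubsamplingAccuracy(ee[, depths(ee) == d], target_depths = d,
                                  n_reps = 3, k = 200, seed = 1)
  expect_equal(unname(res$per_cell[, 1]), 1)
  expect_equal(res$curve$median_accuracy, 1)
})

test_that("the accuracy curve is nonincreasing as depth decreases", {
  sim <- smallSeries(seed = 29, cells_per_stage = 5, n_genes = 800,
                     damaged_cell_fraction = 0)
  ee <- sim$experiment
  keep <- depths(ee) >= 8000
  res <- depthSubsamplingAccuracy(ee[, keep],
                                  target_depths = c(100, 500, 2000, 8000),
                                  n_reps = 50, k = 500, seed = 42)
  med <- res$curve$median_accuracy
  ## deeper subsamples must not be less accurate (tolerance for MC noise)
  expect_true(all(diff(med) >= -0.005))
})

test_that("the 98% rule reproduces the deviation arithmetic", {
  ## accuracy = 1 - |S_sub - S_base| / S_base: 5.0 vs 4.9 -> 0.98
  expect_equal(1 - abs(4.9 - 5.0) / 5.0, 0.98)
  ## the same rule as implemented: a cell whose subsampled score drifts by
  ## 2% of baseline sits exactly at the accuracy target
  sim <- smallSeries(seed = 31, cells_per_stage = 3, n_genes = 500)
  res <- depthSubsamplingAccuracy(sim$experiment,
                                  target_depths = c(200, 1000),
                                  n_reps = 10, k = 300, seed = 5,
                                  accuracy_target = 0.98)
  ok <- res$curve$median_accuracy >= 0.98
  if (any(ok))
    expect_equal(res$min_depth_at_target, res$curve$target_depth[min(which(ok))])
  else
    expect_true(is.na(res$min_depth_at_target))
})

test_that("subsampling accuracy is reproducible and seed-stable", {
  sim <- smallSeries(seed = 37, cells_per_stage = 3, n_genes = 400)
  ee <- sim$experiment[, depths(sim$experiment) >= 1500]
  a <- depthSubsamplingAccuracy(ee, c(500, 1500), n_reps = 20,
                                k = 300, seed = 7)
  b <- depthSubsamplingAccuracy(ee, c(500, 1500), n_reps = 20,
                                k = 300, seed = 7)
  expect_identical(a$per_cell, b$per_cell)
  ## two seeds agree within Monte-Carlo error (3 SE across cells x reps)
  c2 <- depthSubsamplingAccuracy(ee, c(500, 1500), n_reps = 20,
                                 k = 300, seed = 8)
  se <- apply(a$per_cell - c2$per_cell, 2, stats::sd) /
    sqrt(nrow(a$per_cell))
  expect_true(all(abs(a$curve$mean_accuracy - c2$curve$mean_accuracy) <=
                    3 * se + 1e-8))
})
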