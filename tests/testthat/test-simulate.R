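test_that("the generator is bit-reproducible from its seed", {
  a <- smallSeries(seed = 71, cells_per_stage = 4, n_genes = 300)
  b <- smallSeries(seed = 71, cells_per_stage = 4, n_genes = 300)
  expect_identical(as.matrix(.counts(a$experiment)),
                   as.matrix(.counts(b$experiment)))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c2 <- smallSeries(seed = 72, cells_per_stage = 4, n_genes = 300)
  expect_false(identical(as.matrix(.counts(a$experiment)),
                         as.matrix(.counts(c2$experiment))))
})

test_that("spec validation rejects infeasible parameters", {
  expect_error(syntheticSpec(zipf_range = c(1.4, 0.6)), "s_min < s_max")
  expect_error(syntheticSpec(mito_fraction_by_stage = 0.95,
                             ribosomal_fraction = 0.2), "below 1")
  expect_error(syntheticSpec(pseudogene_mismap_fraction = 1.2), "fractions")
  expect_error(syntheticSpec(read_duplication_mean = 0.5), ">= 1")
})

test_that("phi = 0 leaves every pseudogene row identically zero", {
  sim <- smallSeries(seed = 73, cells_per_stage = 5, n_genes = 300,
                     pseudogene_mismap_fraction = 0)
  pg <- .counts(sim$experiment)[names(sim$pseudogene_map), ]
  expect_equal(sum(pg), 0)
})

test_that("the corrector exactly inverts the generator's mismapping", {
  sim <- smallSeries(seed = 79, cells_per_stage = 6, n_genes = 400,
                     pseudogene_mismap_fraction = 0.35)
  ee <- sim$experiment
  ## mismapping moved counts but conserved depth
  corrected <- correctPseudogenes(ee, sim$pseudogene_map)
  expect_identical(depths(corrected), depths(ee))
  rd <- SummarizedExperiment::rowData(ee)
  mito_counts <- Matrix::colSums(.counts(corrected)[rd$is_mito %in% TRUE, ])
  expect_equal(unname(mito_counts), unname(sim$truth$true_mito_counts))
  pg <- .counts(corrected)[names(sim$pseudogene_map), ]
  expect_equal(sum(pg), 0)
})

test_that("a constant exponent yields statistically flat median scores", {
  ## hold every stage-varying knob fixed: constant exponent AND constant
  ## mitochondrial mass
  sim <- simulateMaturationSeries(
    syntheticSpec(n_stages = 3, cells_per_stage = 40, n_genes = 1500,
                  zipf_range = c(0.9, 0.9000001),
                  mito_fraction_by_stage = 0.15, damaged_cell_fraction = 0,
                  pseudogene_mismap_fraction = 0, seed = 83))
  sc <- entropyScores(sim$experiment, k = 1000)
  rk <- sim$metadata$timepoint_rank
  meds <- tapply(sc$score, rk, median)
  sds <- tapply(sc$score, rk, stats::sd)
  n <- tapply(sc$score, rk, length)
  ## stage medians fall within each other's ~3-SE bands
  se <- 1.25 * sds / sqrt(n)   # SE of a median, normal approximation
  expect_lt(max(meds) - min(meds), 3 * (max(se) + min(se)))
})

test_that("expected score decreases strictly in the zipf exponent", {
  scores <- vapply(c(0.7, 1.0, 1.3), function(s) {
    sim <- simulateMaturationSeries(
      syntheticSpec(n_stages = 2, cells_per_stage = 30, n_genes = 1500,
                    zipf_range = c(s, s + 1e-7), damaged_cell_fraction = 0,
                    pseudogene_mismap_fraction = 0, seed = 89))
    median(entropyScores(sim$experiment, k = 1000)$score)
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("damaged cells carry their labels and signatures", {
  sim <- smallSeries(seed = 97, cells_per_stage = 40, n_genes = 500,
                     damaged_cell_fraction = 0.2)
  tr <- as.data.frame(sim$truth)
  expect_equal(sum(tr$damaged), round(0.2 * nrow(tr)))
  dom <- tr$cell_id[tr$damage_type == "dominated"]
  m <- .counts(sim$experiment)
  top1 <- vapply(dom, function(cid) max(m[, cid]) / sum(m[, cid]), numeric(1))
  expect_true(all(top1 >= 0.55))
})

test_that("read duplication preserves molecules and collapses back exactly", {
  sim <- smallSeries(seed = 101, cells_per_stage = 5, n_genes = 300)
  umi <- sim$experiment
  reads <- simulateUMIDuplication(umi, read_duplication_mean = 4, seed = 5)
  expect_identical(datatype(reads), "reads")
  ## every gene/cell entry has at least as many reads as molecules, and the
  ## nonzero pattern is identical (collapsing reproduces the UMI matrix)
  mu <- .counts(umi); mr <- .counts(reads)
  expect_true(all(mr@x >= mu@x))
  expect_identical(mr@i, mu@i)
  expect_identical(mr@p, mu@p)
  expect_true(all(depths(reads) >= depths(umi)))
  ## mean duplication 1 is the identity
  same <- simulateUMIDuplication(umi, read_duplication_mean = 1, seed = 5)
  expect_identical(.counts(same), mu)
  expect_error(simulateUMIDuplication(umi, read_duplication_mean = 0.9), ">= 1")
})

test_that("sensitivity pairs share cells and differ only in detection", {
  spec <- syntheticSpec(n_stages = 2, cells_per_stage = 10, n_genes = 1200,
                        damaged_cell_fraction = 0,
                        pseudogene_mismap_fraction = 0, seed = 103)
  pair <- simulateSensitivityPair(spec, sensitivities = c(300, 900))
  expect_identical(colnames(pair$low), colnames(pair$high))
  expect_true(all(detectedGenes(pair$low) <= 300))
  expect_true(all(detectedGenes(pair$low) <= detectedGenes(pair$high)))
  ## the low-sensitivity protocol flags low coverage at k = 1000
  sc <- entropyScores(pair$low, k = 1000)
  expect_true(all(sc$low_coverage))
  expect_error(simulateSensitivityPair(spec, sensitivities = c(900, 300)),
               "g1 < g2")
})
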