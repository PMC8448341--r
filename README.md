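# entropyScore

Batch-robust transcriptomic entropy scoring of cell maturation from
single-cell RNA-seq counts.

## The problem

Pluripotent stem-cell-derived tissues — PSC-derived cardiomyocytes in
particular — are chronically immature, and assessing *how* immature requires
placing them on the endogenous developmental trajectory rather than
comparing them to an in vitro control. Published scRNA-seq datasets span
protocols (full-length reads vs 3' UMIs), mapping pipelines, and depths, so
most expression-level metrics are swamped by batch effects. This package
implements a per-cell maturation metric built for exactly that setting: a
Shannon entropy of each cell's own gene-expression proportions, computed
over the cell's top 1000 highest-expressed genes,

    S = − Σ_i P_i log P_i ,   P_i = c_i / Σ_j c_j   (i, j in the top-K set)

Immature cells spread counts broadly (high entropy); maturation narrows the
distribution and the score falls. Because S uses only within-cell
proportions of the high-expressed end of the library, it is invariant to
uniform amplification (reads vs UMIs), insensitive to protocol detection
sensitivity below the top-K boundary, and computable one cell at a time —
no dataset integration required. Around the score, the package ships the
full workflow needed to make it comparable across studies:

* **Ingest** — 10x-style MatrixMarket triplets, dense tables, GTF or flat
  gene annotation, pseudogene maps, per-cell metadata (`readCounts`,
  `readGeneTable`, `readPseudogeneMap`, `readCellMetadata`).
* **Gene curation** — correction of mitochondrial reads mismapped to
  nuclear pseudogenes (NUMTs), biotype filtering, removal of
  protocol-biased ribosomal-protein genes (`correctPseudogenes`,
  `filterBiotypes`, `removeRibosomal`).
* **Quality control** — group-normalized depth and top-5-gene metrics with
  fixed cross-study thresholds, dataset-level mitochondrial screening,
  depth-subsampling robustness curves (`cellQCMetrics`, `normalizeQC`,
  `filterCells`, `datasetMitoFlag`, `depthSubsamplingAccuracy`).
* **Calibration** — the gene-subsampling scan behind the choice K = 1000
  and read/UMI concordance checks (`geneSubsamplingScan`, `selectK`,
  `umiCollapseRatio`).
* **Reference staging** — building ordered maturation references and
  placing query populations on them (`buildReference`, `stageCells`).
* **Simulation** — a generator producing maturation-graded count matrices
  with known ground truth (`simulateMaturationSeries` and friends), used
  throughout the tests.

Data live in an `EntropyExperiment` (a validated `SingleCellExperiment`
subclass: integer counts, unique ids, declared reads/UMI datatype).

## Worked example

```r
library(entropyScore)

sim <- simulateMaturationSeries(
  syntheticSpec(cells_per_stage = 50, n_genes = 2000, seed = 7))
ee <- sim$experiment
ee
#> EntropyExperiment: 2000 genes x 300 cells [umi]
#>   depth: median 10217.5 (range 830-47845); detected genes: median 1353
#>   annotated genes: 2000; mito: 13; ribosomal: 80
#>   studies: 1; timepoints: 6

res <- runWorkflow(ee, pseudogeneMap = sim$pseudogene_map,
                   min_genes = 500, seed = 7)
head(as.data.frame(res$scores[, c("cell_id", "score", "n_genes_pooled", "depth")]), 3)
#>           cell_id    score n_genes_pooled depth
#> cell0001 cell0001 6.468022           1000 17805
#> cell0002 cell0002 6.505961           1000  7539
#> cell0004 cell0004 6.509667           1000  8280

md <- as.data.frame(sim$metadata)
stage <- md$timepoint_label[match(res$scores$cell_id, md$cell_id)]
round(tapply(res$scores$score, stage, median), 3)
#> stage01 stage02 stage03 stage04 stage05 stage06
#>   6.498   6.054   5.488   4.836   4.170   3.586
```

The six stage medians fall monotonically from 6.50 to 3.59 nats: the
simulated series matures, and the score recovers the ordering exactly
(Spearman rho = −1). Staging a query population against a reference built
from these cells:

```r
ref <- buildReference(res$scores, md)
query <- res$scores[stage %in% c("stage02", "stage03"), ]
as.data.frame(stageCells(query, ref))[ ,
    c("median_score", "stage_below", "stage_above", "interp", "stage_call")]
#>       median_score stage_below stage_above    interp stage_call
#> query     5.531152     stage02     stage03 0.9237191    stage03
```

The pooled query's median (5.53 nats) sits 92% of the way from the stage-2
median toward the stage-3 median, so it is called stage 3 — the kind of
statement used to benchmark PSC-derived cells against an in vivo
trajectory.

A thin command-line wrapper with subcommands (`simulate`, `curate`, `qc`,
`score`, `subsample-depth`, `calibrate`, `stage`, `run`) is installed at
`inst/cli/entropyscore.R`.

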