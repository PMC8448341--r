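---
title: "Transcriptomic entropy scoring of cell maturation: methods and design"
author: "entropyScore maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptomic entropy scoring of cell maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Post-mitotic maturation — the process by which a committed cell such as a
nascent cardiomyocyte acquires adult structure and function — is accompanied
by a gradual narrowing of the gene-expression distribution: immature cells
spread their transcriptional output over many pathways, mature cells
concentrate it on the machinery they need (sarcomere, calcium handling,
oxidative phosphorylation). This package quantifies that narrowing per cell
with a Shannon entropy,

$$S \;=\; -\sum_{i \in \mathrm{top}K} P_i \log P_i, \qquad
  P_i = \frac{c_i}{\sum_{j \in \mathrm{top}K} c_j},$$

where $c_i$ are the cell's counts and the summation runs over the cell's
$K = 1000$ highest-expressed genes. High entropy means a broad, immature
profile; entropy falls monotonically as the distribution narrows. Because
$S$ depends only on within-cell proportions, the score is computed from one
cell at a time — no smoothing, no integration — which is what makes it
usable across studies with wildly different batch structure.

Key properties of the estimator, all enforced by tests:

* **Scale invariance.** Multiplying a cell's counts by any positive integer
  (uniform amplification, e.g. PCR duplication) leaves the score
  bit-identical. We compute $P_i$ as exact count ratios rather than via
  logarithmic prefix identities precisely so that $cv/(cT)$ rounds to the
  same double as $v/T$.
* **Sensitivity standardization.** Genes strictly below the top-$K$ boundary
  never enter the score. Two protocols that detect 3000 vs 7000 genes per
  cell but agree on the high-expressed end therefore agree on the score,
  while a full-gene entropy separates them purely on detection sensitivity.
* **Bounds.** $0 \le S \le \log(\min(K, G_\mathrm{detected}))$; the upper
  bound is attained exactly on uniform top-$K$ cells.

## Why the within-subset renormalization

"Entropy of the top 1000 genes" admits two readings: renormalize the
proportions within the subset, or keep full-library proportions and truncate
the sum. We renormalize within the subset. This makes the $\log K$ bound
exact, makes the sensitivity-invariance property above hold exactly rather
than approximately, and leaves the score a genuine entropy of a probability
distribution. The alternative is not exposed because the two differ by a
factor and an additive term that depend on the discarded tail mass — exactly
the protocol-sensitive quantity top-$K$ subsetting is meant to remove.

Ties at the $K$-th position are broken lexicographically by gene id in
`topKSubset()` for determinism; the score itself is tie-insensitive (tied
boundary genes have equal counts, so which one enters the pool cannot change
the value).

Scores are reported in nats (natural log) by default and the base is
configurable. Cells detecting fewer than $K$ genes are scored over all
detected genes and flagged (`low_coverage`); datasets where this is the norm
should be treated with caution rather than rescaled.

## The curation steps and their order

1. **Pseudogene correction** (`correctPseudogenes`). Nuclear insertions of
   mitochondrial sequence (NUMTs) siphon mitochondrial counts under
   pipelines that count multi-mapping reads. Counts of each mapped
   pseudogene are added back to its canonical mitochondrial gene, cell-wise;
   depth is conserved exactly. This must precede biotype filtering —
   filtering first would destroy the mismapped counts instead of reassigning
   them.
2. **Biotype filtering** (`filterBiotypes`). Default keep-set:
   protein-coding, antisense, lncRNA. Unannotated genes are dropped with a
   message by default (annotation versions drift across public datasets); a
   strict mode errors instead.
3. **Ribosomal-protein removal** (`removeRibosomal`). Ribosomal-protein
   fractions are strongly protocol-dependent (droplet and STRT-style
   libraries run systematically higher), so these genes are excluded from
   the score. Identification is by symbol pattern (`^Rp[sl]` mouse,
   `^RP[SL]` human — deliberately excluding mitochondrial ribosomal
   `Mrpl/Mrps`), overridable with an explicit list.

Cell QC (`cellQCMetrics`) is computed after step 1 but before steps 2–3:
mitochondrial and ribosomal counts are genuine evidence about cell quality
even though they are excluded from the score itself.

## Standardized QC

Per cell we compute depth, detected genes, the top-5-gene fraction (lysed or
degraded cells are dominated by a handful of transcripts) and the
mitochondrial fraction. Cross-study comparability comes from normalizing
within (study, timepoint) groups: each measurement is divided by its group
median. The depth statistic is reported as `log2(depth / group median)` and
the top-5 statistic as a plain ratio; these scales are what make a single
pair of cross-study thresholds (retain `norm_depth >= -0.5`,
`norm_top5 <= 1.3`, both inclusive, plus `n_genes > 1000` strict)
meaningful. Both functional forms are configurable; the defaults are chosen
so that the thresholds express "below ~71% of group-median depth" and "30%
above group-median top-5 load".

Dataset-level screening flags studies whose median cell mitochondrial
fraction is an outlier among datasets: above `median + 3 * MAD` of the
per-dataset medians (`stats::mad`, consistency constant 1.4826), or above a
fixed user threshold. The MAD fence is this package's operationalization of
a judgment call; it is deliberately conservative and reported, never
silently applied.

## Depth robustness

`depthSubsamplingAccuracy` downsamples each library without replacement
(multivariate hypergeometric — discarding reads from the observed library,
not binomial thinning) and reports per-cell accuracy
$1 - |S_\mathrm{sub} - S_\mathrm{base}| / S_\mathrm{base}$, median across
cells, with an accuracy target of 0.98 (about a 0.1 shift on a 5-nat
score). The curve is only a meaningful robustness statement while the
subsampled libraries still detect more than ~1000 genes: once the pool
shrinks below $K$ the deviation changes sign and the curve is provably
non-monotone. Analyses in this package therefore restrict target depths to
the admissible regime, the same restriction used when the procedure is
applied to real data.

## Calibrating K

`geneSubsamplingScan` scores every cell at each candidate $K$ and reports
two criteria: the Spearman correlation between per-(study, timepoint) median
scores and developmental rank (too large a $K$ re-admits sensitivity
differences and degrades it) and the variance of min–max-scaled
per-timepoint medians (too small a $K$ compresses the dynamic range and
shrinks it). Population variance is used — the choice is immaterial because
selection is tolerance-based, but it is documented in the output.
`selectK` returns the $K$ jointly within tolerance of both optima, breaking
ties toward 1000 and then toward smaller $K$; tolerance comparisons carry a
`sqrt(.Machine$double.eps)` cushion so exact boundary grids behave
inclusively. The default 1000 is kept as the cross-study convention; the
scan is how a user would check it on their own data.

Datatype robustness is checked by `umiCollapseRatio`: the same cells scored
from pre-collapse read counts and from UMI counts should give per-cell
ratios near 1. Uniform duplication gives exactly 1 by scale invariance;
realistic overdispersed duplication moves it only through rank changes deep
in the top-$K$ pool.

## Reference staging

`buildReference` aggregates QC-passed, scored, stage-labeled cells into
ordered per-stage summaries (median, quartiles, cell and study counts);
monotone decrease of the medians is expected but not enforced — wobbles are
reported, not hidden. `stageCells` places a query group's median between
the bracketing stage medians with a linear interpolation coordinate;
queries outside the range are clamped to the end stage and flagged
`beyond-reference`. Group-median placement is the default because
dataset-level correspondences ("this PSC-CM line scores like late embryo")
are the robust, reportable unit; a per-cell mode exists. Cross-species
placement is permitted and always labeled with the reference species.
References serialize to versioned CSV so they can be shared without the
underlying cells.

## The synthetic-data generator

`simulateMaturationSeries` generates the structure the method assumes, so
every pipeline stage is testable without downloads:

* **Narrowing distributions.** Nuclear gene probabilities follow a Zipf
  profile $P(r) \propto r^{-s}$ over a fixed ranking, with $s$ rising
  linearly from 0.6 to 1.4 across six stages (defaults). A power law
  matches the heavy-tailed look of real per-cell distributions and gives a
  single maturation knob.
* **Depths** are log-normal, median 10,000 counts (meanlog `log(1e4)`,
  sdlog 0.3) — a mid-range UMI protocol.
* **Composition.** Mitochondrial mass ramps 5% to 30% across stages
  (mitochondrial content rises with cardiomyocyte maturation); ribosomal
  mass is a protocol property (default 10%); a fraction φ = 0.25 of each
  mitochondrial gene's counts is emitted under a paired NUMT pseudogene id
  (binomial per entry, depth-conserving, exactly invertible by
  `correctPseudogenes` with the generator's own map).
* **Damage.** 5% of cells are injected as damaged: half subsampled to 10%
  depth, half with their top gene boosted to 60% of depth; truth labels are
  returned so QC sensitivity can be measured.
* **Protocol sensitivity** truncates detection to each cell's top-$g$
  sampled genes; `simulateSensitivityPair` draws one base series and
  truncates it at two ceilings (defaults 3000 vs 7000 detected genes) so
  the pair is matched cell-for-cell. Ceilings only bind on deep libraries,
  so the pair demonstration uses a depth median of 100,000 counts —
  full-length-protocol scale.
* **Read duplication.** `simulateUMIDuplication` amplifies each molecule
  into `1 + Geometric` reads (mean 4 by default), the simplest
  overdispersed amplification model; collapsing reproduces the UMI matrix
  exactly by construction.

What the generator does **not** emulate: gene–gene correlation structure,
cell-type mixtures, ambient RNA, doublets, batch-specific gene dropout
biases, or any fitted real reference. Passing tests on synthetic data
therefore demonstrate the algebraic and statistical properties of the
pipeline — conservation, invariance, monotone recovery of a known maturation
ordering, QC discrimination of injected damage — not biological validity on
any particular tissue.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script run the default series (6
stages x 200 cells x 8000 genes), a 600-cell deep-library sensitivity pair,
a 30-cell x 4000-gene depth-subsampling study (50 replicates per depth), and
a 300-cell calibration scan — sizes chosen as the smallest at which the
stochastic assertions (Spearman <= -0.95, Monte-Carlo accuracy bands) are
stable across seeds. Other conventions: `0 log 0 = 0`; probability vectors
must sum to 1 within 1e-6; zero-depth cells are an error at scoring and a
flagged row (never a silent drop) in QC; all generator randomness is
reproducible from a single integer seed, and RNG state of the caller is
always restored.

## Known limitations

* The score is a relative staging metric, not an absolute clock; placements
  are only meaningful against a reference built with the same $K$, log
  base, and curation.
* Cells detecting far fewer than $K$ genes compress the dynamic range;
  datasets where the median detected genes is near or below $K$ should be
  excluded rather than rescaled (the `low_coverage` flag and QC make this
  visible).
* The pseudogene correction requires a curated cross-mapping table; the
  package validates and applies such tables but does not discover
  cross-mappings from sequence.
* The MAD-based dataset flag assumes several datasets; with fewer than two
  it refuses and a fixed threshold must be chosen.
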