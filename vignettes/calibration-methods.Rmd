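---
title: "Pseudobatch calibration of batch-correction methods: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudobatch calibration: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(batchcal)
```

## The calibration idea

A batch-correction method maps a dataset plus batch labels to a corrected
object. If the labels are pure noise — a random partition of one homogeneous
dataset into two "pseudobatches" — a well-calibrated method should return
the data essentially unchanged: there is nothing to correct. `batchcal`
constructs exactly this null, applies a corrector, and measures what
changed at the three places where downstream analysis actually consumes the
data: the neighbor structure of the embedding, the Leiden clustering, and
per-gene differential-expression (DE) calls. Each experiment is repeated
(default 25 iterations, each with a fresh random split and its own seed)
and medians across iterations are reported, so a single unlucky split
cannot dominate.

Two perturbation baselines calibrate the metrics themselves. The *injected
batch effect* (thinning the counts of the top-100 marker genes of one
cluster, in one pseudobatch only, to 50%) is a positive control: metrics
must move when a real artifact is present, and they must move more as the
thinning factor drops from 1 to 0.75 to 0.5. *Batch downsampling* (thinning
every count of one batch to 50%) bounds the harmless change a pure depth
difference produces.

## What the simulator emulates — and what it does not

Real droplet datasets cannot ship with a package, so the generator stands
in for them. Counts for cell $i$, gene $g$ are negative binomial with mean
$s_i \mu_g f(t_i, g)$: $s_i$ is a log-normal library-size factor
($\sigma = 0.35$), $\mu_g$ a gamma-distributed base mean (shape 2, mean 1
count/cell) so that highly-variable-gene selection has a realistic spread to
work with, and $f = 2^{\text{marker\_log2fc}}$ when $g$ is a marker of cell
$i$'s type (1 otherwise). The dispersion (NB size) defaults to 1, in the
range typical of UMI data. A configurable fraction of genes (default 2%)
carries the "MT-" prefix so the mitochondrial QC filter has something to
act on; their expression model is not otherwise special. Marker sets are
disjoint across types, and cell types are balanced.

The defaults — 2000 cells × 1000 genes, 3 types, 50 markers per type at
log2 fold change 2 — are the study conditions used by the package's own
tests and by `scripts/acceptance.R`. They are deliberately modest: large
enough that Leiden recovers the types exactly and the hurdle test has full
power on markers, small enough that a complete five-iteration calibration
experiment runs in minutes on one CPU.

What the simulator does *not* emulate, and therefore what passing tests do
not establish about real data: no doublets or ambient RNA, no
continuous/trajectory structure (types are discrete), no gene–gene
correlation beyond cell type and library size, no batch-specific chemistry.
A corrector that is calibrated here can still misbehave on real data whose
structure violates these simplifications; the harness accepts any MTX/TSV
dataset precisely so users can rerun the experiment on their own matrices.

## The uncorrected reference workflow

Ground truth is the standard pipeline on the unaltered counts, computed
once per iteration before the split: library-size normalization to 10,000
counts with `log1p`; the top 2000 highly variable genes by mean-binned
normalized dispersion (20 bins, z-scored log dispersion — the
Seurat-flavoured scheme); column-centered PCA to 50 components on the HVG
submatrix; the exact Euclidean 15-NN graph; Leiden with the modularity
objective at resolution 1. The same HVG list and the same Leiden seed are
reused when the corrected data are re-embedded and re-clustered, so any
difference is attributable to the corrector, not to pipeline randomness.

Choices worth flagging:

* **QC defaults** (≥200 genes/cell, ≥3 cells/gene, ≤5% mitochondrial) are
  the canonical tutorial thresholds; they are configuration, applied once
  before the experiment, and the simulated defaults pass them comfortably.
* **PCA sign convention**: each component's largest-magnitude loading is
  made positive. Neighbor ranks are invariant to any orthogonal
  transformation, but a fixed convention makes runs bit-reproducible.
* **k-NN ties** are broken by cell index ascending; with continuous
  embeddings ties essentially never occur, but the tie rule makes the
  brute-force oracle comparison exact.
* **Leiden labels** are renumbered by descending cluster size so label
  identity is stable across runs with the same seed.

## Rank displacement

For cell $i$, take its top-$k$ neighbors in the reference embedding
($k = 30$), find each one's rank in the post-correction embedding's full
distance ordering (self excluded, ties by index), and record the median of
the $k$ absolute rank differences; the summary is the median over cells.
Ranks are computed against *all* cells, not within the k-NN graph, so a
displaced neighbor can land anywhere up to rank $n - 1$; per-cell values
are half-integers in $[0, n-2]$. For correctors returning counts, the
"after" embedding is PCA on the corrected matrix over the same HVG list;
for embedding-returning correctors it is the corrector's own embedding;
graph-only correctors have no embedding and the metric is recorded as
skipped with a reason rather than silently omitted. The per-iteration
median is taken first, then the median across iterations (both are stored).

## Cluster comparison

The confusion matrix counts cells in each (before-cluster, after-cluster)
pair. Columns are reordered by maximum-weight linear assignment (an $O(n^3)$
Hungarian solve; surplus columns appended by descending total) — a
reproducible stand-in for ordering the display "as diagonal as possible" by
hand. Each square also reports the fraction of its cells from pseudobatch
A; by construction of the random split this should be near 0.5, and squares
with fewer than 10 cells are flagged as dimmed because their ratios are
noise. The Adjusted Rand Index is computed from the pair-counting
contingency-table formula; in the degenerate case where the permutation
model's denominator vanishes (both partitions trivial) it is defined as 1
when the partitions are identical as partitions and 0 otherwise.

## The hurdle DE model

Single-cell expression is zero-inflated, so each gene is modelled in two
parts over the cells of the two compared clusters only: a logistic
regression of the detection indicator (normalized value > 0) on the design
covariates, and a Gaussian linear model of the value among detected cells.
Two designs are supported — expression on cluster, and on batch + cluster —
and a covariate is tested by a likelihood-ratio statistic summing the two
parts' deviance differences, referred to a χ² with the summed degrees of
freedom (2 when both parts are estimable for a two-level covariate). A part
that cannot be estimated — detection constant, fewer than 3 detected cells,
or the covariate confounded within the part — contributes 0 with 0 df; if
neither part is estimable the gene is flagged invalid and excluded from the
Bonferroni denominator, which is α = 0.05 over the number of genes with a
valid result.

Numerical choices:

* **Ridge on the logistic part** (default $10^{-3}$ on non-intercept
  coefficients, configurable): genes detected in only one cluster are
  perfectly separated and would otherwise give infinite estimates; the
  penalized likelihood-ratio statistic stays finite and enormous, which is
  the right answer. The same penalized objective is what the independent
  `optim()`-based oracle in the tests maximizes.
* **Sufficiency aggregation**: with categorical covariates the likelihood
  depends on the data only through per-covariate-pattern counts and sums,
  so both parts are fitted at pattern level (≤4 rows); the per-gene cost is
  independent of cell count, and fits shared between the three reported
  tests (cluster | cluster-only, cluster | batch+cluster,
  batch | batch+cluster) are computed once.
* **Gaussian LRT** uses the MLE form $N \log(\mathrm{RSS}_0 /
  \mathrm{RSS}_1)$ with a tiny additive floor so an exactly-zero residual
  sum cannot produce NaN.
* **No empirical-Bayes shrinkage**: the reference tools shrink the
  continuous-part variance across genes; this implementation deliberately
  does not, keeping the statistic self-contained. At the sample sizes used
  here (hundreds of cells per cluster) the difference is immaterial for
  calibration; at very small $n$ per cluster the unshrunk test loses power
  on sparsely detected genes.
* **log2 fold change** is the difference of mean log2-scale expression with
  zeros included — antisymmetric, zero for identical groups, and defined
  even for genes the hurdle model rejects as invalid.
* **Marker ranking** (used to identify the compared clusters and to pick
  injection targets) is a one-vs-rest Wilcoxon rank-sum test, one-sided in
  the upregulated direction so a depleted gene never counts as a marker,
  with normal approximation, tie and continuity corrections; ties in the
  ranking break by larger fold change, then gene index. Clusters are
  matched across runs by the rule "carries the marker gene within the
  top-200"; when a marker resolves nowhere (or both markers to the same
  cluster) the iteration's DE block is recorded as skipped, not silently
  dropped.

Under the pseudobatch null the batch covariate's p-values are approximately
uniform. One caveat the tests respect: for a *single* fixed split the
per-gene tests are weakly correlated through shared cells (library-size
factors), so the dispersion of the "fraction of p < 0.05" statistic around
0.05 is slightly wider than binomial; across splits it centers correctly.

## Harness semantics

The random split assigns ⌈n/2⌉ cells to batch A (the extra cell of an odd
dataset goes to A), uniformly at random given the seed. Relabeling A↔B
maps every imbalance ratio $r \to 1 - r$, so imbalance is summarized as
$|r - 0.5|$. QC runs once before the experiment; preprocessing runs per
iteration. A corrector that throws marks its iteration failed — the error
is stored, the iteration is excluded from medians, and only an experiment
with *no* successful iteration errors out. Every iteration derives all of
its randomness (split, Leiden, thinning) from `base_seed + i`, making
reports bit-reproducible; the embedded dataset fingerprint lets
`compare_reports()` warn when reports from different datasets are mixed.

The "uncorrected counts with corrected clusters" DE variant isolates where
DE drift comes from: if significant-gene sets change only when the
corrected *matrix* is used, the corrector altered expression profiles; if
they change with corrected *clusters* on original counts, it altered
cluster membership.

## Built-in correctors

* `identity` — the null hypothesis made executable; every metric has a
  known fixed point (0 displacement, ARI 1, overlap 100%) that the
  acceptance tests assert exactly.
* `location_scale` — per gene and batch, standardize to pooled mean and SD
  on the normalized scale (zero-variance genes are mean-shifted only). A
  plain linear baseline, deliberately without empirical-Bayes shrinkage; it
  is *not* a reimplementation of any published method. Its known calibration
  failure — manufacturing a batch association in the detection pattern by
  shifting exact zeros — is exactly the kind of artifact the harness is
  built to expose, and makes it a useful non-trivial test article.
* `oracle_inverse` — exactly undoes a deterministic (exact-mode) injection
  on the normalized scale; only meaningful in tests, where recovering the
  unperturbed matrix to $10^{-9}$ and all identity fixed points is asserted
  end to end.

External methods attach through `register_corrector()` by declaring which
object they consume (raw counts, normalized counts, embedding, k-NN graph)
and returning the corrected object; results are validated (finite values,
unchanged cell universe — shuffled cell order is realigned by id, negative
raw counts rejected) before any metric sees them. Adapters for specific
published tools are intentionally out of scope.

## Injection and downsampling semantics

"Reducing counts to 50%" is implemented as binomial thinning
$c \to \mathrm{Binomial}(c, f)$ rather than deterministic halving: outputs
stay integer-valued, thinning at $a$ then $b$ equals thinning at $ab$ in
distribution, and the operation models what deeper-vs-shallower sequencing
actually does to UMI counts. Read-level downsampling of raw sequencing data
is approximated by the same UMI-level thinning — the standard desk-scale
surrogate that preserves the count model. A deterministic `exact` mode
(multiply by $f$, possibly fractional) exists solely so the oracle-inverse
corrector can be exact; experiments default to thinning.

## Problem sizes and limitations

The test suite exercises the full pipeline at 2000 × 1000 (five
iterations), the DE calibration at 400 cells × 2000 genes, power at 600
cells × 500 genes over 20 seeds, and the severity sweep at 800 × 500 over
10 seeds per factor — sizes chosen so the complete suite and the
acceptance script each run in a few minutes on one CPU while keeping every
asymptotic approximation (χ², rank-sum normality) comfortably in range.
Known limitations: no sparse-matrix fast path (dense matrices bound
practical size to a few thousand cells); exact k-NN is quadratic in cells;
the DE stage supports exactly the two printed designs rather than a general
formula interface; and the simulator's independence assumptions mean
real-data pathologies (ambient RNA, doublets, nested batch structure) are
untested here by construction.
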