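---
title: "Benchmarking class-discovery pipelines for two-channel microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking class-discovery pipelines for two-channel microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustgrid)
```

## The problem

Unsupervised clustering of samples is a routine first analysis of expression
data: given arrays from, say, a cancer cohort, can the expression profiles
alone recover clinically meaningful groups? Before any clustering runs, an
analyst has made a chain of choices — how to normalize the raw two-channel
scans, how to treat flagged spots and missing values, which genes (or how
many principal components) to cluster on, whether to z-scale genes, and
which clustering algorithm to use. Each choice is defensible in isolation;
their joint effect on whether the true classes are found is what this
package is built to measure.

`clustgrid` implements that measurement as a factorial benchmark for
two-channel (common reference) microarray experiments with two known
classes. A *cluster analysis* here is one path through five consecutive
sub-processes:

1. **Normalization** — one of `no.norm`, `norm.pt`, `norm.pt.bkg`,
   `norm.glob`, `norm.glob.bkg`: raw log-ratios, or print-tip/global
   MA-loess, each with or without background correction.
2. **Imputation** — `ROW` (gene median) or `SVD` (iterative eigengene
   regression), after filtering out samples with ≥ 50% and genes with
   ≥ 30% missing values.
3. **Gene selection** — `STD`, `M`, `T1` at N ∈ {15, 100, 1000} genes,
   `PC` at k ∈ {3, 5, 15} components, or `NONE` (13 unsupervised
   selections), plus the supervised positive controls `T2` and `Mdiff`.
4. **Standardization** — per-gene z-scaling, on or off.
5. **Clustering** — six hierarchical variants (Euclidean / Manhattan /
   correlation distance × Ward / average linkage), k-means, PAM under two
   metrics, a one-dimensional SOM, and Gaussian-mixture clustering
   (Mclust, only with ≤ 500 features).

Crossing these and removing the invalid Mclust combinations gives 2780
unsupervised analyses (1280 more with the supervised selections), each
producing a sample partition that is scored against the known classes.

## Scoring: the merge-optimized adjusted Rand index

For partitions $P$ and $Q$ of $n$ samples, the Rand index is the fraction
of sample pairs on which the partitions agree:
$\mathrm{Rand} = (a + b)/\binom{n}{2}$, with $a$ pairs together in both and
$b$ pairs apart in both. The adjusted Rand index centers this at its chance
expectation and rescales to a maximum of 1:

$$\mathrm{aRand} = \frac{\mathrm{Rand} - E[\mathrm{Rand}]}
{\max(\mathrm{Rand}) - E[\mathrm{Rand}]},$$

computed here in the standard Hubert–Arabie permutation-model form from the
contingency table (cost $O(st)$, not $O(n^2)$; the test suite checks it
against explicit pair enumeration). When the denominator vanishes (both
partitions all singletons, or both a single group) the value is defined as
1 for identical partitions and 0 otherwise.

Fixing the predicted cluster count at the true class count punishes methods
for outliers that occupy clusters of their own — something an analyst would
shrug off when reading a dendrogram. The evaluation therefore predicts
**ten** clusters and exhaustively joins them into two groups, keeping the
bipartition (of $2^{c-1}-1$ candidates, 511 for $c = 10$) that maximizes
aRand against the truth. Ties are broken by the lexicographically smallest
label set in the first group, so results are reproducible. Because the
merge optimizes over bipartitions, its null expectation is positive;
`null_distribution()` simulates it (uniform assignment of samples to ten
labels, default 1000 replicates) and reports the median and 95th
percentile as reference lines.

## The synthetic-data generator

Real cohorts of this design (40–133 samples, 8,000–40,000 spots) cannot
ship with a package, so every stage is exercised against
`simulate_experiment()`, which emulates their structure with known truth:

- **Common-reference model.** A reference intensity per gene is drawn
  log-normally (log2 scale, mean 10, sd 1.5); the sample channel equals the
  reference times $2^{M}$, so M-values have exactly the log-ratio semantics
  the pipeline assumes.
- **Class structure.** A configurable number of genes is differentially
  expressed with between-class shift `de_effect` (log2 units), half up- and
  half down-regulated, split symmetrically about zero so the expected
  between-class difference equals `de_effect`.
- **Dye bias.** An additive offset in M, $b(A) = \mathrm{amp}\,(\sin(2\pi
  (A - A_{\min})/\mathrm{range}(A)) + 0.5\,(A - \bar A)/\mathrm{range}(A))$:
  a smooth curved MA-trend of the kind loess normalization is designed to
  remove, and removable to near zero so the normalization property tests
  are meaningful.
- **Print-tip structure.** Spots are laid out in contiguous blocks; each
  array draws independent per-block offsets (SD `block_offset_sd`).
- **Artifacts.** Gamma-distributed additive background in both channels,
  Bernoulli flagging, missing-completely-at-random spots (foregrounds
  zeroed, so they are recovered as missing by the M/A computation), and a
  fraction of genes printed twice under one gene ID to exercise duplicate
  collapsing.

Defaults are fixed at values typical for such studies — 60 samples (30 per
class), 8000 genes, 5% differentially expressed at a 1 log2-unit shift,
dye-bias amplitude 0.3, 16 blocks, 2% flagged and 2% missing spots — and
configurations in which flagging plus missingness would necessarily exceed
the 50% sample filter are rejected outright. What the generator does *not*
emulate: biological covariance between genes, spatial artifacts beyond
block offsets, and one-channel platforms. Passing tests therefore certify
the machinery and its statistical behavior under a clean generative model,
not performance on any particular real cohort.

## Numerical and design choices

- **Loess dye-effect fit**: local linear regression (degree 1) with
  span 0.3 and four robustness iterations (Tukey biweight). Span 0.3 is the
  conventional MA-loess setting and, measured on the generator's
  one-period sine bias, removes the planted curve to a maximum residual
  below 0.1 where span 0.4 leaves ~0.15. Fits require at least 30
  non-missing spots (per block for the print-tip variants) and fail with an
  error naming the array/block otherwise; a fit on spots whose A-values all
  coincide degenerates to the constant median. Evaluation outside the
  fitted A-range is held at the boundary.
- **`no.norm`** is the raw foreground log-ratio: background correction is
  paired only with the normalization methods. The `.bkg` variants recompute
  *both* M and A from the corrected intensities, and spots with signal
  below background become missing.
- **Filtration** evaluates the 50%/30% thresholds strictly (`<`) and in a
  single pass on the input mask: removing a bad sample never changes which
  genes are kept. An iterated fixed-point variant is available behind
  `iterate = TRUE`.
- **SVD imputation** defaults: k = 10 eigengenes (capped at one below the
  smaller matrix dimension), relative Frobenius-change tolerance 0.01,
  iteration cap 100 (the per-iteration change is recorded in the
  `svd_trace` attribute; hitting the cap warns and returns the last
  iterate). Observed cells are never modified.
- **Moderated variance** for the t-type selections:
  $\sigma^2_{\mathrm{modif}} = (\nu_0 \sigma_0^2 + (n-1) s^2)/(\nu_0+n-2)$
  with prior strength $\nu_0 = 10$ and $\sigma_0^2$ the mean sample
  variance of the 101 genes nearest in rank of mean expression (a global
  prior is available). $\nu_0 = 0$ short-circuits to the plain sample
  variance — also for classes of size two, where the shrinkage denominator
  would vanish — making the statistics verifiable against textbook t
  formulas.
- **Selection determinism**: ties at the top-N cutoff break by ascending
  gene ID (making selections nested in N); principal-component signs are
  fixed so each component's largest-magnitude loading is positive.
  Standardization is crossed with PC selection in the grid for fidelity to
  the factorial design, even though z-scaling is motivated for gene
  features.
- **Ward on non-Euclidean distances** uses the `ward.D2` criterion applied
  to the dissimilarities as supplied — the pragmatic convention under which
  combining Ward with Manhattan or correlation distances is meaningful.
- **k-means** is Hartigan–Wong, best of 100 random starts by within-cluster
  sum of squares. **SOM** is a one-dimensional chain of 10 units trained
  for 100 epochs with learning rate decaying linearly 0.05 → 0.01 and a
  Gaussian neighborhood shrinking to radius 1, initialized along the first
  principal axis. **Mclust** fits spherical and diagonal covariance
  families only ({EII, VII, EEI, VVI}), since full covariances are singular
  when the feature count approaches the sample count; EM is initialized
  from model-based hierarchical clustering and failures surface as recorded
  failure rows in the grid, never crashes.
- **Determinism**: all stochastic steps (generator, k-means, SOM, null
  simulation, per-run grid seeds) run under seeds derived from a master
  seed and restore the caller's RNG state. Deterministic methods are
  invariant to sample order up to relabeling; the seeded stochastic methods
  are order-invariant only in distribution, since the consumed random
  stream interacts with input order.

## Meta-analysis

`variance_decomposition()` regresses aRand on the categorical sub-process
factors plus dataset, with all second-order interactions, and reports each
term's share of the total sum of squares from the sequential (Type I)
ANOVA table. Because Type I shares depend on term order, the canonical
order (dataset, normalization, standardization, imputation, selection,
clustering — then the induced interaction order) is fixed and configurable;
factors with a single observed level are dropped, and inestimable
interaction cells are handled by the fit's pivoting.

`eliminate_methods()` implements the iterative reduction: within each of
the sub-processes normalization, gene selection and clustering, every pair
of surviving methods is compared by a two-sided Wilcoxon signed-rank test
on aRand values paired over identical settings of everything else
(dataset included), restricted to settings valid for both methods — the
restriction matters because Mclust is undefined for large selections.
P-values are Bonferroni-multiplied by the number of tests in the current
iteration (a cumulative variant is available); if the minimum corrected
p-value is below 0.001 the pair's lower-median method is removed with all
its analyses, and the procedure repeats until nothing more is removed. The
removal order, corrected p-values and superior methods are returned as a
trace. The paired Wilcoxon uses the normal approximation throughout, as
ties between paired aRand values are common.

## Problem sizes used in the tests

The packaged suites run entirely on generated data: partition-metric
fuzzing at up to 50 objects, merge-search verification for up to ten
clusters (511 bipartitions) against exhaustive enumeration, nulls at 40 and
100 samples with 1000 replicates, supervised-recovery runs at 60 samples ×
2000 genes over ten seeds, and a full reduced 288-specification grid over
three synthetic cohorts of 60 samples × 2000 genes. These sizes sit at the
lower end of the designs the generator emulates and were chosen so the
whole suite re-runs comfortably on a laptop; all statistical conclusions
they support were reproduced at the generator's larger defaults during
development.

## Known limitations

- The generator's independence between genes makes selection easier than on
  real arrays, where co-regulation creates correlated noise; absolute aRand
  levels on synthetic data are therefore optimistic.
- The elimination procedure inherits the ambiguities of its description:
  the pairing unit, the meaning of "least favorable" (here: lower paired
  median) and the Bonferroni universe (here: per-iteration) had to be fixed
  by convention; alternatives are exposed as options.
- Only two-channel common-reference designs are covered; no between-array
  normalization, quantile/variance-stabilizing methods, consensus
  clustering, or automatic cluster-number selection.
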