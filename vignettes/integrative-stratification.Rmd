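---
title: "Integrative two-modality patient stratification with omicstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative two-modality patient stratification with omicstrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicstrat)
```

## The problem

Molecular stratifications of a cancer cohort disagree across measurement
modalities: clustering patients on mRNA expression and on miRNA
expression typically yields different, partially overlapping subgroup
structures. Rather than forcing a consensus, `omicstrat` keeps both
stratifications and models their relationship explicitly, so that
subgroups defined by the *joint* cluster membership — "mRNA cluster 1
**and** miRNA cluster 2" — can be formed and tested against clinical
outcome. This matters because survival signal can live entirely in the
interaction: each modality's clusters may mix prognoses identically
while the joint cells differ sharply.

The workflow has three phases, each a pure function of its inputs and
seeds: per-modality clustering with quality diagnostics, cross-modality
integration into a parallel-sets model, and survival comparison of
selected subgroups.

## Data model and preprocessing

Expression data enter as features × samples matrices with unique IDs;
the clinical table carries per-sample survival time, a 0/1 event status
(1 = death/event observed, 0 = right-censored), age and tumor grade. All
three inputs are restricted to their shared sample set, in one common
order, before anything else happens.

Preprocessing is deliberately pinned rather than configurable-by-vague
convention: the optional log transform is `log2(x + 1)` (requires
non-negative input), and the optional per-feature normalization is a
z-score with the *population* (divide-by-n) standard deviation.
Zero-variance features become all-zero rows with a warning rather than
NaNs. Duplicated feature rows in input files are collapsed by their
mean, the common microarray convention; cells that cannot be parsed at
all are an error, while rows with missing cells are dropped — imputation
is out of scope. Sample matching is exact string equality on IDs; no
barcode-truncation heuristics are applied.

Feature selection is user-driven: a comma-delimited list per modality
restricts the matrix (in list order) before clustering. Unmatched names
warn rather than fail, mirroring tolerant list entry; the package ships
a 10-miRNA list (`inst/extdata/mirna_features.txt`) usable end-to-end on
synthetic cohorts. There is deliberately no automatic feature ranking.

## Clustering

Three algorithms cover the common practice spectrum:

* **k-means** on the sample columns, with k-means++ initialization, Lloyd
  iterations and 10 restarts (default), keeping the lowest total
  within-cluster sum of squares; ties keep the first minimum
  encountered. Deterministic given the seed.
* **Spectral clustering**: an affinity matrix (Gaussian RBF kernel with
  sigma = the median pairwise Euclidean distance — the standard
  heuristic — or Pearson correlation shifted to `(1 + r) / 2` to keep it
  non-negative), symmetrically normalized; the top-k eigenvectors are
  row-normalized and clustered with the same seeded k-means.
* **Community detection**: Louvain modularity maximization on the
  thresholded similarity graph. The number of clusters is emergent.
  Isolated vertices cannot inform modularity, so they are pooled into a
  single "unassigned" cluster given the last label.

Labels are always canonicalized by order of first appearance along the
sample sequence: cluster 1 contains the first sample, and rerunning any
method with the same configuration reproduces labels byte-for-byte.
This stability is what makes block/ribbon references in selection files
meaningful across runs.

Cluster quality is assessed with the silhouette statistic computed on
**squared** Euclidean distances (not plain Euclidean — the squared form
is the package's definition throughout), with `b(i)` taken as the mean
dissimilarity to the nearest other cluster and singleton clusters
scoring 0. The cluster-ordered matrix export (columns grouped by label,
with cumulative block boundaries) is the data layer a blocked heatmap
would render; no graphics are produced.

## The similarity graph

The population-structure view is a graph with one vertex per patient.
Pearson correlation is a similarity already; Euclidean distance is
converted through `s = 1 / (1 + d)`, a bounded, order-reversing map into
`(0, 1]`, so a single global threshold rule — keep edges with
`s > threshold`, strictly — serves both metrics. The threshold has no
universally correct default and is a required analysis choice; raising
it can only remove edges (monotonicity is tested). Layout is seeded
Fruchterman–Reingold (300 iterations by default), scaled into the unit
square, with isolated vertices placed on a surrounding ring — a package
convention chosen so they remain visible without distorting the
connected component's geometry. A single-vertex graph sits at (0.5, 0.5).

## The parallel-sets model

Two clusterings over the same sample sequence cross-tabulate into
blocks (one per cluster per axis) and ribbons (one per non-empty
contingency cell, carrying its member IDs). Geometry is normalized to
`[0, 1]`: per axis, block heights are `count / n` of the usable length
`1 − gap·(k − 1)`, stacked in canonical label order with uniform gaps;
within each block, ribbon stubs stack in opposite-axis label order.
Both orderings are stability-first conventions — no ribbon-crossing
minimization is attempted, because stable references beat visual
optimization in a batch tool. Empty cells produce no ribbon. Three
invariants are asserted on every build: ribbon counts sum to n, each
block's ribbon marginal equals its count, and the member sets partition
the cohort.

Subgroups are the union of selected blocks and/or ribbons (overlaps
de-duplicate silently), plus a complement operation for
"group X vs everyone else" comparisons. Selections may overlap each
other as objects; disjointness is enforced only where it matters, at
survival comparison time.

## Survival comparison

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package behind the module's own containers: the product-limit
curve per subgroup (events precede censorings at tied times, the
standard convention) and the G-group log-rank chi-squared on G − 1
degrees of freedom, with per-group observed and expected event counts
reported. P-values are kept at full double precision. No multiple-testing
correction is applied across a user's repeated exploratory comparisons —
each p-value is per-comparison, and users testing many subgroup
combinations should adjust externally. Cox regression and covariate
adjustment are out of scope; age and grade are carried descriptively.

## The synthetic cohort generator

The generator exists so that every pipeline stage has a ground truth.
Each sample draws a joint latent label (i, j) from a `k_mrna × k_mirna`
mixing table; modality matrices are cluster mean profiles plus Gaussian
noise; survival is exponential with the joint label's hazard, censored
by an independent exponential. Choices worth knowing:

* **Signal placement**: each cluster shifts a random half of its
  modality's features by ± `effect_size/2` standard deviations (random
  sign), leaving the other half at baseline. Unshifted features act as
  noise, so feature selection genuinely matters.
* **Baseline 8, noise sd 1**: log2-intensity-like values, kept
  non-negative so the log-transform path is exercisable.
* **Exponential survival and censoring**: closed-form expectations and
  cheap simulation; no distributional claim about real cohorts is
  intended.
* **Explicit mixing table**: both dependent and independent
  cross-modality regimes are representable, since real per-modality
  stratifications are typically *not* independent.

The packaged `interaction_scenario(seed)` fixes n = 240, 2×2 joint
labels, uniform mixing, hazards {(1,1): 0.2, (1,2): 1.0, (2,1): 1.0,
(2,2): 0.2}, effect size 6, noise sd 1, censor rate 0.1. The hazard
table is the point: each marginal's two clusters mix {0.2, 1.0}
identically, so single-modality splits are null by construction while
the joint diagonal-vs-off-diagonal split carries a five-fold hazard
ratio.

What the generator does **not** emulate: real-data marginal
distributions, batch effects, miRNA–mRNA regulatory correlation, or
non-proportional hazards. Passing tests on synthetic cohorts
demonstrate the pipeline's correctness and statistical calibration
under its stated model, not performance on any real cohort.

## Numerical and testing choices

Problem sizes in the test and acceptance suites are chosen to keep the
whole suite in the tens of seconds while leaving no statistical
ambiguity: cluster recovery uses n = 200 with effect size 6 (where the
adjusted Rand index against truth must be exactly 1 over 20 seeds, and
|ARI| < 0.1 at zero effect), log-rank calibration uses 500 null
replicates of 50-per-arm cohorts (empirical rejection at α = 0.05
expected in [0.03, 0.075]), and the interaction scenario is replicated
100 times (combined stratification must beat both marginals in ≥ 90).
The statistical core is checked against independent oracles: hand
product-limit and hypergeometric O/E/V derivations for KM and the
log-rank statistic, and a brute-force silhouette implementation at 1e-9.

Determinism is treated as a contract: every random step takes an
explicit seed, RNG state is saved and restored around seeded sections,
and artifacts are written with fixed 10-significant-digit formatting so
reruns are byte-identical.

## Limitations

* Two axes only; the model stores axes as a list so a third modality is
  an additive extension, with ribbons defined pairwise between adjacent
  axes.
* The graph threshold, k, and the clustering method remain analysis
  choices; silhouette output guides but does not automate them.
* Survival comparisons are exploratory; see the note on multiplicity
  above.
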