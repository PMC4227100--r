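# omicstrat

Integrative two-modality patient stratification, batch style.

Cancer cohorts profiled on two molecular modalities — typically mRNA and
miRNA expression — often stratify differently depending on which modality
you cluster. `omicstrat` makes that disagreement itself the object of
analysis: it clusters the cohort independently per modality, models the
cross-modality relationship as a *parallel sets* structure (per-cluster
blocks on two axes, ribbons for every non-empty contingency cell), lets
you combine blocks and ribbons into named patient subgroups, and compares
those subgroups' clinical outcomes with Kaplan–Meier curves and the
log-rank test. The interesting case is an *interaction*: subgroups defined
by the joint (mRNA, miRNA) cluster membership can separate survival far
better than any single-modality split.

The package is aimed at computational biologists who want the
click-driven exploration of integrative stratification tools as a
reproducible, scriptable pipeline.

## The statistics under the hood

- **Per-modality clustering** of samples: k-means (k-means++ seeding,
  Lloyd iterations, best of 10 restarts by within-cluster sum of
  squares), normalized-Laplacian spectral clustering, or Louvain
  community detection on a thresholded patient-similarity graph.
- **Silhouette validation** with dissimilarity = *squared* Euclidean
  distance: s(i) = (b(i) − a(i)) / max(a(i), b(i)), where a(i) is the
  mean dissimilarity to the sample's own cluster and b(i) that to the
  nearest other cluster.
- **Parallel-sets model**: block heights and ribbon widths proportional
  to patient counts; ribbon (i, j) carries the patients in mRNA cluster i
  and miRNA cluster j. Conservation (Σ ribbons = n, marginals = blocks)
  is asserted on every build.
- **Survival comparison**: Kaplan–Meier product-limit estimates
  S(t) = Π (1 − dᵢ/nᵢ) and the (multi-group) log-rank test,
  χ² = (O−E)ᵀV⁻¹(O−E) on G−1 degrees of freedom, via the `survival`
  package.
- **Synthetic cohorts**: latent joint subtypes drive cluster-specific
  mean shifts in both modalities and exponential survival hazards with
  exponential right-censoring, so the whole pipeline is testable without
  any external data.

## Worked example

The packaged *interaction scenario* generates a 240-patient cohort with
2×2 joint subtypes, uniform mixing and hazard table
{(1,1): 0.2, (1,2): 1.0, (2,1): 1.0, (2,2): 0.2} — each modality's two
clusters mix the hazards identically, so only the joint stratification
carries survival signal.

```r
library(omicstrat)

co <- interaction_scenario(seed = 7)
a  <- kmeans_cluster(co$mrna,  k = 2, seed = 1)
b  <- kmeans_cluster(co$mirna, k = 2, seed = 1)
a
#> <cluster_assignment> modality=mRNA method=kmeans k=2 n=240 sizes=131/109

silhouette_scores(co$mrna, a)$overall_mean
#> [1] 0.837...

m <- layout_parallel_sets(cross_tabulate(a, b), gap = 0.02)
m$ribbons[, c("label_a", "label_b", "count", "width")]
#>   label_a label_b count     width
#> 1       1       1    66 0.2750000
#> 2       1       2    65 0.2708333
#> 3       2       1    47 0.1958333
#> 4       2       2    62 0.2583333

concordant <- select_subgroup(m, "concordant", ribbons = list(c(1, 1), c(2, 2)))
discordant <- complement_subgroup(m, concordant, "discordant")
compare_subgroups(co$clin, list(concordant, discordant))$test
#> <logrank_result> chi-squared = 93.0431 on 1 df, p = 5.1169e-22
```

The mean silhouette of 0.84 says both modalities cluster cleanly; the
four ribbons are near-uniform (each ≈ a quarter of the cohort), so
neither clustering predicts the other; and the ribbon-combined subgroups
separate survival at p ≈ 5×10⁻²², while the same comparison on either
single-modality split is non-significant (try
`select_subgroup(m, "g1", blocks = list(c(1, 1)))` against its
complement: p ≈ 0.94 on this cohort).

The same analysis runs from a shell via the thin CLI in `exec/`:

```sh
Rscript exec/omicstrat simulate cohort/ --spec interaction --seed 7
Rscript exec/omicstrat cluster   config.yaml
Rscript exec/omicstrat integrate config.yaml selections.yaml
```

with declarative YAML selections replacing interactive clicks. See the
vignette (`vignettes/integrative-stratification.Rmd`) for the model,
parameter and design discussion.

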