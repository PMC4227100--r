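Package: omicstrat
Title: Integrative Two-Modality Patient Stratification with Parallel Sets
    and Survival Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless, scriptable workflow for integrative patient
    stratification from two expression modalities (e.g. mRNA and miRNA).
    Clusters a cohort independently per modality (k-means, spectral
    clustering, or graph community detection), validates clusters with
    silhouette scores on squared Euclidean distances, models the
    cross-modality cluster relationships as a parallel-sets structure of
    blocks and ribbons, resolves declarative subgroup selections into
    patient sets, and compares subgroup outcomes with Kaplan-Meier curves
    and the log-rank test. Includes a synthetic-cohort generator with
    latent subtypes driving both modalities and survival, and a batch
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    igraph,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
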