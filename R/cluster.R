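#' Cluster assignment container
#'
#' Per-sample integer labels in `1..k` for one modality, together with the
#' method and parameters that produced them. Labels are canonicalized by
#' order of first appearance along the sample sequence, so repeated runs
#' with the same configuration are byte-identical and downstream block
#' ordering is stable.
#'
#' @param modality Modality tag.
#' @param sample_ids Character vector of sample IDs, one per label.
#' @param labels Integer labels; every value in `1..max(labels)` must occur.
#' @param method One of `"kmeans"`, `"spectral"`, `"community"`.
#' @param params Named list of parameters (k requested, seed, ...).
#' @return An object of class `cluster_assignment`.
#' @export
cluster_assignment <- function(modality, sample_ids, labels, method,
                               params = list()) {
  labels <- as.integer(labels)
  if (length(labels) != length(sample_ids))
    stop("labels and sample_ids differ in length")
  k <- max(labels)
  if (min(labels) < 1L || !all(seq_len(k) %in% labels))
    stop("labels must cover 1..k with every cluster non-empty")
  structure(list(modality = modality, sample_ids = as.character(sample_ids),
                 labels = labels, k = k, method = method, params = params),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> modality=%s method=%s k=%d n=%d sizes=%s\n",
              x$modality, x$method, x$k, length(x$labels),
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

# Relabel so cluster 1 contains the first sample, cluster 2 the first
# sample not in cluster 1, etc.
canonical_labels <- function(labels) match(labels, unique(labels))

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# k-means++ seeding: spread initial centers with probability proportional
# to squared distance from the nearest center already chosen.
kmpp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rep(Inf, n)
  for (j in seq_len(k)[-1]) {
    last <- X[idx[j - 1], , drop = FALSE]
    d2 <- pmin(d2, rowSums(sweep(X, 2, as.numeric(last))^2))
    idx[j] <- if (all(d2 == 0)) sample.int(n, 1)
              else sample.int(n, 1, prob = d2)
  }
  X[idx, , drop = FALSE]
}

# Best-of-n_restarts Lloyd k-means with k-means++ seeding. Ties in total
# within-cluster sum of squares keep the first-encountered minimum.
# Assumes the RNG seed has been fixed by the caller.
kmeans_best <- function(X, k, n_restarts) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmpp_centers(X, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 100,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop("k-means failed on every restart (degenerate input?)")
  best
}

#' k-means clustering of samples
#'
#' Clusters the samples (columns) of an expression matrix with Lloyd
#' k-means, k-means++ initialization and multiple restarts, keeping the
#' solution with the lowest total within-cluster sum of squares.
#' Deterministic given `seed`.
#'
#' @param m An [expr_matrix] (already feature-selected / preprocessed).
#' @param k Number of clusters, `2 <= k <= n_samples`.
#' @param seed RNG seed.
#' @param n_restarts Number of k-means++ restarts (default 10).
#' @return A [cluster_assignment].
#' @export
kmeans_cluster <- function(m, k, seed = 1, n_restarts = 10) {
  X <- t(m$values)
  n <- nrow(X)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  fit <- with_seed(seed, kmeans_best(X, k, n_restarts))
  cluster_assignment(m$modality, m$sample_ids, canonical_labels(fit$cluster),
                     method = "kmeans",
                     params = list(k = k, seed = seed, n_restarts = n_restarts))
}

# Sample-affinity matrix for spectral clustering. Pearson correlations are
# shifted to (1+r)/2 so the affinity is non-negative; the RBF kernel uses
# sigma = median pairwise Euclidean distance.
spectral_affinity <- function(m, similarity) {
  if (similarity == "pearson") {
    if (length(m$feature_ids) < 2)
      stop("pearson similarity needs at least 2 features")
    sds <- apply(m$values, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance sample column(s): ",
           paste(m$sample_ids[sds == 0], collapse = ", "))
    (1 + stats::cor(m$values)) / 2
  } else {
    d <- as.matrix(stats::dist(t(m$values)))
    sigma <- stats::median(d[upper.tri(d)])
    if (!is.finite(sigma) || sigma == 0)
      stop("degenerate similarity: all samples identical")
    exp(-d^2 / (2 * sigma^2))
  }
}

#' Spectral clustering of samples
#'
#' Normalized-Laplacian spectral clustering: builds a sample-affinity
#' matrix, takes the top-k eigenvectors of the symmetrically normalized
#' affinity, row-normalizes the embedding, and runs the same seeded
#' k-means as [kmeans_cluster] in embedded space.
#'
#' @inheritParams kmeans_cluster
#' @param similarity Affinity kernel: `"pearson"` (shifted to `[0,1]`) or
#'   `"euclidean_rbf"` (Gaussian kernel, sigma = median pairwise distance).
#' @return A [cluster_assignment].
#' @export
spectral_cluster <- function(m, k, seed = 1,
                             similarity = c("euclidean_rbf", "pearson"),
                             n_restarts = 10) {
  similarity <- match.arg(similarity)
  n <- length(m$sample_ids)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  S <- spectral_affinity(m, similarity)
  dvec <- rowSums(S)
  M <- S / sqrt(outer(dvec, dvec))
  U <- eigen(M, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  fit <- with_seed(seed, kmeans_best(U, k, n_restarts))
  cluster_assignment(m$modality, m$sample_ids, canonical_labels(fit$cluster),
                     method = "spectral",
                     params = list(k = k, seed = seed, similarity = similarity,
                                   n_restarts = n_restarts))
}

#' Community detection on a patient-similarity graph
#'
#' Louvain modularity maximization on a sparsified [similarity graph]
#' [sparsify]. The number of clusters is emergent. Isolated vertices do
#' not enter the modularity optimization: they are pooled into a single
#' "unassigned" cluster that receives the last label.
#'
#' @param g A `similarity_graph` (see [sparsify]) with at least one edge
#'   and non-negative edge weights.
#' @param seed RNG seed for the (seeded) Louvain pass.
#' @param modality Modality tag recorded on the assignment (defaults to
#'   the graph's metric tag).
#' @return A [cluster_assignment] with `method = "community"`.
#' @export
community_cluster <- function(g, seed = 1, modality = "expr") {
  if (nrow(g$edges) == 0) stop("similarity graph has no edges")
  if (any(g$edges$weight < 0))
    stop("community detection requires non-negative edge weights")
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$sample_ids[g$edges$i], to = g$sample_ids[g$edges$j],
               weight = g$edges$weight),
    directed = FALSE,
    vertices = data.frame(name = g$sample_ids))
  memb <- with_seed(seed, igraph::cluster_louvain(ig)$membership)
  iso <- igraph::degree(ig) == 0
  labels <- integer(length(memb))
  labels[!iso] <- canonical_labels(memb[!iso])
  if (any(iso)) labels[iso] <- max(labels[!iso], 0L) + 1L
  cluster_assignment(modality, g$sample_ids, labels, method = "community",
                     params = list(seed = seed, threshold = g$threshold,
                                   n_unassigned = sum(iso)))
}

#' Silhouette validation of a clustering
#'
#' Per-sample silhouette scores with dissimilarity measured by the
#' *squared* Euclidean distance between samples in the current feature
#' space: `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, where `a(i)` is the
#' mean dissimilarity to the sample's own cluster and `b(i)` the mean
#' dissimilarity to the nearest other cluster. Members of singleton
#' clusters score 0.
#'
#' @param m The [expr_matrix] the clustering was computed on.
#' @param assign A [cluster_assignment] over the same samples.
#' @return An object of class `silhouette_report`: list with
#'   `per_sample_scores` (named, in `[-1, 1]`), `per_cluster_mean`,
#'   `overall_mean`, and `ordering` (sample indices sorted by cluster then
#'   descending score, the order a silhouette bar plot uses).
#' @export
silhouette_scores <- function(m, assign) {
  if (!identical(m$sample_ids, assign$sample_ids))
    stop("matrix and assignment sample ids differ")
  if (assign$k < 2) stop("silhouette requires at least 2 clusters")
  d2 <- as.matrix(stats::dist(t(m$values)))^2
  sil <- cluster::silhouette(assign$labels, dmatrix = d2)
  scores <- sil[, "sil_width"]
  names(scores) <- m$sample_ids
  per_cluster <- vapply(seq_len(assign$k),
                        function(cl) mean(scores[assign$labels == cl]),
                        numeric(1))
  structure(list(per_sample_scores = scores,
                 per_cluster_mean = per_cluster,
                 overall_mean = mean(scores),
                 ordering = order(assign$labels, -scores)),
            class = "silhouette_report")
}

#' Cluster-ordered matrix (heatmap backing data)
#'
#' Permutes the columns of an expression matrix so samples are grouped by
#' cluster label 1..k (stable within cluster), and reports the cumulative
#' block boundaries — the data layer behind a cluster-blocked heatmap.
#'
#' @inheritParams silhouette_scores
#' @return List with `matrix` (column-permuted [expr_matrix]) and
#'   `boundaries` (integer vector of cumulative cluster sizes).
#' @export
ordered_matrix <- function(m, assign) {
  if (!identical(m$sample_ids, assign$sample_ids))
    stop("matrix and assignment sample ids differ")
  ord <- order(assign$labels)
  list(matrix = subset_samples(m, m$sample_ids[ord]),
       boundaries = cumsum(tabulate(assign$labels, assign$k)))
}
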