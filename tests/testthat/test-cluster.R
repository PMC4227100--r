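test_that("kmeans_cluster finds the WCSS-optimal 2-partition of 1-D blobs", {
  x <- c(0, 0.1, 0.2, 10, 10.1)
  m <- em(matrix(x, 1, 5))
  cl <- kmeans_cluster(m, k = 2, seed = 3)
  oracle <- brute_best_2partition(x)
  expect_equal(ari(cl$labels, as.integer(oracle)), 1)
  expect_equal(cl$labels, c(1L, 1L, 1L, 2L, 2L))  # canonical labels
})

test_that("kmeans_cluster edge cases: k = n, k out of range", {
  m <- em(matrix(c(1, 5, 9, 14), 1, 4))
  cl <- kmeans_cluster(m, k = 4, seed = 1)
  expect_equal(sort(unique(cl$labels)), 1:4)
  expect_error(kmeans_cluster(m, k = 1), "at least 2")
  expect_error(kmeans_cluster(m, k = 5), "exceeds")
})

test_that("clustering is deterministic given the seed and canonical", {
  blobs <- gen_blobs(30, 3, seed = 5)
  a <- kmeans_cluster(blobs$m, k = 3, seed = 42)
  b <- kmeans_cluster(blobs$m, k = 3, seed = 42)
  expect_identical(a$labels, b$labels)
  expect_equal(a$labels[1], 1L)  # first sample defines cluster 1
  s1 <- spectral_cluster(blobs$m, k = 3, seed = 42)
  s2 <- spectral_cluster(blobs$m, k = 3, seed = 42)
  expect_identical(s1$labels, s2$labels)
})

test_that("kmeans recovers well-separated blobs across seeds", {
  for (seed in c(1, 7, 19, 33, 101)) {
    blobs <- gen_blobs(60, 3, sep = 20, sd = 1, seed = seed)
    cl <- kmeans_cluster(blobs$m, k = 3, seed = seed)
    expect_equal(ari(cl$labels, blobs$labels), 1)
  }
})

test_that("spectral clustering recovers blobs and block-diagonal affinity", {
  blobs <- gen_blobs(40, 2, sep = 20, sd = 1, seed = 9)
  cl <- spectral_cluster(blobs$m, k = 2, seed = 1)
  expect_equal(ari(cl$labels, blobs$labels), 1)
  clp <- spectral_cluster(blobs$m, k = 2, seed = 1, similarity = "pearson")
  expect_equal(ari(clp$labels, blobs$labels), 1)

  expect_error(spectral_cluster(blobs$m, k = 99, seed = 1), "exceeds")
  ident <- em(matrix(1, 4, 6) + 0)  # all samples identical
  expect_error(spectral_cluster(ident, k = 2, seed = 1), "degenerate|zero-variance")
})

test_that("community detection recovers cliques and merges isolated vertices", {
  # two disjoint 4-cliques (+ one isolated vertex) as a similarity graph
  n <- 9
  S <- diag(n)
  for (i in 1:4) for (j in 1:4) S[i, j] <- 0.9
  for (i in 5:8) for (j in 5:8) S[i, j] <- 0.9
  diag(S) <- 1
  rownames(S) <- colnames(S) <- paste0("P", 1:n)
  g <- sparsify(S, 0.5)
  cl <- community_cluster(g, seed = 1)
  expect_equal(cl$labels[1:4], rep(1L, 4))
  expect_equal(cl$labels[5:8], rep(2L, 4))
  expect_equal(cl$labels[9], 3L)  # isolated -> unassigned, labelled last
  expect_equal(cl$k, 3L)

  # single triangle -> one community
  S3 <- matrix(0.9, 3, 3); diag(S3) <- 1
  rownames(S3) <- colnames(S3) <- paste0("Q", 1:3)
  cl3 <- community_cluster(sparsify(S3, 0.5), seed = 1)
  expect_equal(cl3$k, 1L)

  expect_error(community_cluster(sparsify(diag(3), 0.5)), "no edges")
})

test_that("two bridged 5-cliques split at the modularity optimum", {
  n <- 10
  A <- matrix(0, n, n)
  A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1; diag(A) <- 0
  A[5, 6] <- A[6, 5] <- 1  # bridge
  rownames(A) <- colnames(A) <- paste0("V", 1:n)
  S <- A * 0.9; diag(S) <- 1
  g <- sparsify(S, 0.5)
  cl <- community_cluster(g, seed = 2)
  expect_equal(cl$k, 2L)
  expect_equal(ari(cl$labels, rep(1:2, each = 5)), 1)

  # brute-force oracle: best modularity over all 2-partitions is the cliques
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  best_q <- -Inf; best <- NULL
  for (mask in 1:(2^n - 2)) {
    memb <- as.integer(as.logical(bitwAnd(mask, 2^(0:(n - 1))))) + 1L
    q <- igraph::modularity(ig, memb)
    if (q > best_q) { best_q <- q; best <- memb }
  }
  expect_equal(ari(best, rep(1:2, each = 5)), 1)
  expect_equal(igraph::modularity(ig, cl$labels), best_q, tolerance = 1e-12)
})

test_that("silhouette matches the hand example and singleton convention", {
  m <- em(matrix(c(0, 1, 10, 11), 1, 4))
  cl <- cluster_assignment("test", m$sample_ids, c(1, 1, 2, 2), "kmeans")
  rep <- silhouette_scores(m, cl)
  # a(1) = 1, b(1) = (100 + 121)/2 = 110.5 under squared Euclidean
  expect_equal(unname(rep$per_sample_scores[1]), 109.5 / 110.5,
               tolerance = 1e-9)
  expect_equal(rep$overall_mean, mean(rep$per_sample_scores))
  expect_true(all(rep$per_sample_scores >= -1 & rep$per_sample_scores <= 1))

  m3 <- em(matrix(c(0, 1, 5), 1, 3))
  cl3 <- cluster_assignment("test", m3$sample_ids, c(1, 1, 2), "kmeans")
  rep3 <- silhouette_scores(m3, cl3)
  expect_equal(unname(rep3$per_sample_scores[3]), 0)  # singleton scores 0

  expect_error(silhouette_scores(m, cluster_assignment("t", m$sample_ids,
                                                       rep(1, 4), "kmeans")),
               "at least 2")
})

test_that("silhouette agrees with a brute-force oracle on random instances", {
  set.seed(202)
  for (rep_i in 1:25) {
    n <- sample(6:30, 1)
    k <- sample(2:3, 1)
    X <- matrix(rnorm(4 * n), 4, n)
    labels <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
    m <- em(X)
    cl <- cluster_assignment("t", m$sample_ids, canonical_labels(labels),
                             "kmeans")
    got <- silhouette_scores(m, cl)$per_sample_scores
    want <- brute_silhouette(X, cl$labels)
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("ordered_matrix groups columns by cluster with stable order", {
  m <- expr_matrix(matrix(1:8, 2, 4), c("F1", "F2"), paste0("s", 1:4))
  cl <- cluster_assignment("t", m$sample_ids, c(2, 1, 2, 1), "kmeans")
  om <- ordered_matrix(m, cl)
  expect_equal(om$matrix$sample_ids, c("s2", "s4", "s1", "s3"))
  expect_equal(om$boundaries, c(2L, 4L))

  sorted <- cluster_assignment("t", m$sample_ids, c(1, 1, 2, 2), "kmeans")
  om2 <- ordered_matrix(m, sorted)
  expect_equal(om2$matrix$sample_ids, m$sample_ids)

  each <- cluster_assignment("t", m$sample_ids, 1:4, "kmeans")
  expect_equal(ordered_matrix(m, each)$boundaries, 1:4)
})
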