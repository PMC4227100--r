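# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation paths.

# Brute-force silhouette with squared Euclidean dissimilarity:
# a(i) = mean d2 to own-cluster co-members, b(i) = min over other clusters
# of mean d2, s(i) = (b - a) / max(a, b); singleton clusters score 0.
brute_silhouette <- function(X, labels) {
  n <- ncol(X)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d2[i, j] <- sum((X[, i] - X[, j])^2)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d2[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d2[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Hand-rolled two-group log-rank: per-event-time hypergeometric O/E/V.
brute_logrank2 <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O1 <- E1 <- V <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1 == 1); d <- d1 + sum(t2 == tt & e2 == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n - d) * n1 * n2 / (n^2 * (n - 1))
  }
  (O1 - E1)^2 / V
}

# Brute-force Kaplan-Meier at the distinct event times (events precede
# censorings at ties, i.e. censored-at-t subjects are still at risk at t).
brute_km <- function(times, events) {
  ets <- sort(unique(times[events == 1]))
  surv <- numeric(length(ets))
  s <- 1
  for (i in seq_along(ets)) {
    at_risk <- sum(times >= ets[i])
    d <- sum(times == ets[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(event_times = ets, surv = surv)
}

# Best k=2 partition of 1-D points by exhaustive WCSS minimization.
brute_best_2partition <- function(x) {
  n <- length(x)
  best <- NULL; best_w <- Inf
  for (mask in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    w <- sum((x[grp] - mean(x[grp]))^2) + sum((x[!grp] - mean(x[!grp]))^2)
    if (w < best_w) { best_w <- w; best <- grp }
  }
  best
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small expr_matrix from a plain matrix with default ids.
em <- function(values, modality = "test") {
  values <- as.matrix(values)
  expr_matrix(values,
              feature_ids = paste0("F", seq_len(nrow(values))),
              sample_ids = paste0("S", seq_len(ncol(values))),
              modality = modality)
}

# Well-separated Gaussian blobs: samples in columns, k clusters.
gen_blobs <- function(n, k, n_features = 10, sep = 20, sd = 1, seed = 1) {
  set.seed(seed)
  labels <- sort(rep_len(seq_len(k), n))
  centers <- matrix(rnorm(n_features * k), n_features, k)
  centers <- apply(centers, 2, function(c) sep * c / sqrt(sum(c^2)))
  vals <- centers[, labels] + matrix(rnorm(n_features * n, sd = sd),
                                     n_features, n)
  list(m = em(vals), labels = labels)
}
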