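#' Sample-similarity matrix
#'
#' Pairwise similarity between samples (columns). `"pearson"` gives the
#' Pearson correlation of sample profiles (in `[-1, 1]`); `"euclidean"`
#' converts the Euclidean distance `d` to the bounded similarity
#' `s = 1 / (1 + d)` in `(0, 1]`, so one thresholding rule applies to both
#' metrics. The diagonal is 1.
#'
#' @param m An [expr_matrix] with at least 2 samples (and at least 2
#'   features for `"pearson"`).
#' @param metric `"pearson"` or `"euclidean"`.
#' @return A symmetric numeric matrix with sample IDs as dimnames and a
#'   `"metric"` attribute.
#' @export
similarity_matrix <- function(m, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  if (length(m$sample_ids) < 2) stop("need at least 2 samples")
  if (metric == "pearson") {
    if (length(m$feature_ids) < 2)
      stop("pearson similarity needs at least 2 features")
    sds <- apply(m$values, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance sample column(s): ",
           paste(m$sample_ids[sds == 0], collapse = ", "))
    S <- stats::cor(m$values)
  } else {
    S <- 1 / (1 + as.matrix(stats::dist(t(m$values))))
  }
  diag(S) <- 1
  dimnames(S) <- list(m$sample_ids, m$sample_ids)
  attr(S, "metric") <- metric
  S
}

#' Sparsify a similarity matrix into a graph
#'
#' Applies a global threshold, keeping only edges whose similarity
#' strictly exceeds it. Isolated vertices are permitted (an edgeless
#' graph is legal here; community detection will refuse it later).
#'
#' @param S Symmetric similarity matrix (from [similarity_matrix]).
#' @param threshold Global similarity threshold; edge `(i, j)` is retained
#'   iff `S[i, j] > threshold`.
#' @return An object of class `similarity_graph`: list with `sample_ids`,
#'   `edges` (data.frame `i`, `j`, `weight` with `i < j`), `metric`,
#'   `threshold` and `layout` (`NULL` until [force_layout] is run).
#' @export
sparsify <- function(S, threshold) {
  if (!isSymmetric(unname(S), tol = 1e-12)) stop("S must be symmetric")
  ids <- rownames(S)
  if (is.null(ids)) ids <- paste0("V", seq_len(nrow(S)))
  keep <- which(upper.tri(S) & S > threshold, arr.ind = TRUE)
  edges <- data.frame(i = keep[, 1], j = keep[, 2],
                      weight = S[keep])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(sample_ids = ids, edges = edges,
                 metric = attr(S, "metric") %||% "unknown",
                 threshold = threshold, layout = NULL),
            class = "similarity_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d vertices, %d edges (metric=%s, threshold=%g)%s\n",
              length(x$sample_ids), nrow(x$edges), x$metric, x$threshold,
              if (is.null(x$layout)) "" else ", with layout"))
  invisible(x)
}

#' Deterministic force-directed layout
#'
#' Fruchterman-Reingold layout of the connected part of the graph, with
#' seeded random initial positions so identical inputs give identical
#' coordinates. The main layout is scaled into the centered square
#' `[0.15, 0.85]^2`; isolated vertices are placed evenly on a ring of
#' radius 0.48 around the center, outside the main mass. A single-vertex
#' graph is placed at the center (0.5, 0.5).
#'
#' @param g A `similarity_graph`.
#' @param seed RNG seed.
#' @param iterations Number of layout iterations (default 300).
#' @return `g` with a `layout` matrix (columns `x`, `y`, rows = samples),
#'   all coordinates in `[0, 1]`.
#' @export
force_layout <- function(g, seed = 1, iterations = 300) {
  n <- length(g$sample_ids)
  coords <- matrix(0.5, n, 2, dimnames = list(g$sample_ids, c("x", "y")))
  if (n > 1) {
    deg <- integer(n)
    if (nrow(g$edges) > 0) {
      tab <- table(factor(c(g$edges$i, g$edges$j), levels = seq_len(n)))
      deg <- as.integer(tab)
    }
    iso <- deg == 0
    if (any(!iso)) {
      ig <- igraph::graph_from_data_frame(
        data.frame(from = g$edges$i, to = g$edges$j, weight = g$edges$weight),
        directed = FALSE, vertices = data.frame(name = seq_len(n)))
      ig <- igraph::induced_subgraph(ig, which(!iso))
      xy <- with_seed(seed, igraph::layout_with_fr(ig, niter = iterations))
      for (d in 1:2) {
        rng <- range(xy[, d])
        xy[, d] <- if (diff(rng) == 0) 0.5
                   else 0.15 + 0.7 * (xy[, d] - rng[1]) / diff(rng)
      }
      coords[!iso, ] <- xy[, 1:2]
    }
    if (any(iso)) {
      k <- sum(iso)
      theta <- pi / 2 + 2 * pi * (seq_len(k) - 1) / k
      coords[iso, 1] <- 0.5 + 0.48 * cos(theta)
      coords[iso, 2] <- 0.5 + 0.48 * sin(theta)
    }
  }
  g$layout <- pmin(pmax(coords, 0), 1)
  g
}

#' Export a similarity graph to TSV files
#'
#' Writes `<prefix>_edges.tsv` (sample_i, sample_j, weight) and
#' `<prefix>_vertices.tsv` (sample_id, plus x/y columns when a layout is
#' present and a label column when a clustering is supplied) — a plain
#' contract any external viewer can consume.
#'
#' @param g A `similarity_graph`.
#' @param prefix Output path prefix.
#' @param assign Optional [cluster_assignment] supplying vertex labels.
#' @return Character vector of the two paths written, invisibly.
#' @export
export_graph <- function(g, prefix, assign = NULL) {
  edge_path <- paste0(prefix, "_edges.tsv")
  vert_path <- paste0(prefix, "_vertices.tsv")
  ed <- data.frame(sample_i = g$sample_ids[g$edges$i],
                   sample_j = g$sample_ids[g$edges$j],
                   weight = sprintf("%.10g", g$edges$weight))
  utils::write.table(ed, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  vd <- data.frame(sample_id = g$sample_ids)
  if (!is.null(g$layout)) {
    vd$x <- sprintf("%.10g", g$layout[, "x"])
    vd$y <- sprintf("%.10g", g$layout[, "y"])
  }
  if (!is.null(assign)) {
    if (!identical(assign$sample_ids, g$sample_ids))
      stop("assignment sample ids differ from graph vertices")
    vd$label <- assign$labels
  }
  utils::write.table(vd, vert_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges = edge_path, vertices = vert_path))
}
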