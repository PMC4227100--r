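#' Cross-tabulate two clusterings into a parallel-sets model
#'
#' Builds the contingency structure between two per-modality clusterings
#' of the same sample sequence: one *block* per cluster on each axis and
#' one *ribbon* per non-empty contingency cell, each ribbon carrying the
#' IDs of the patients assigned to cluster `label_a` in the first modality
#' and `label_b` in the second. Conservation (ribbon counts sum to n,
#' block marginals match) is asserted on every build.
#'
#' @param a,b [cluster_assignment] objects over the identical sample
#'   sequence (use [align_modalities] upstream).
#' @return An object of class `parallel_sets_model`: list with `axes`
#'   (the two assignments), `blocks` (per axis, data.frame `label`,
#'   `count`), `ribbons` (data.frame `label_a`, `label_b`, `count` plus a
#'   `members` list-column), `sample_ids`, `n` and `gap`/geometry fields
#'   filled in by [layout_parallel_sets].
#' @export
cross_tabulate <- function(a, b) {
  if (!identical(a$sample_ids, b$sample_ids))
    stop("the two clusterings cover different sample sequences; align first")
  n <- length(a$sample_ids)
  tab <- table(factor(a$labels, seq_len(a$k)), factor(b$labels, seq_len(b$k)))
  cells <- which(tab > 0, arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  ribbons <- data.frame(label_a = as.integer(cells[, 1]),
                        label_b = as.integer(cells[, 2]),
                        count = as.integer(tab[cells]))
  ribbons$members <- lapply(seq_len(nrow(ribbons)), function(r) {
    a$sample_ids[a$labels == ribbons$label_a[r] & b$labels == ribbons$label_b[r]]
  })
  model <- structure(
    list(axes = list(a, b),
         blocks = list(
           data.frame(label = seq_len(a$k), count = tabulate(a$labels, a$k)),
           data.frame(label = seq_len(b$k), count = tabulate(b$labels, b$k))),
         ribbons = ribbons, sample_ids = a$sample_ids, n = n, gap = NA_real_),
    class = "parallel_sets_model")
  validate_parallel_sets(model)
  model
}

# Conservation invariants, asserted on every model build.
validate_parallel_sets <- function(p) {
  stopifnot(sum(p$ribbons$count) == p$n)
  for (ax in 1:2) {
    lab_col <- c("label_a", "label_b")[ax]
    marg <- vapply(p$blocks[[ax]]$label, function(l) {
      sum(p$ribbons$count[p$ribbons[[lab_col]] == l])
    }, integer(1))
    if (!all(marg == p$blocks[[ax]]$count))
      stop("ribbon marginals do not match block counts on axis ", ax)
  }
  members <- unlist(p$ribbons$members)
  if (anyDuplicated(members) || !setequal(members, p$sample_ids))
    stop("ribbon member sets do not partition the cohort")
  invisible(p)
}

#' @export
print.parallel_sets_model <- function(x, ...) {
  cat(sprintf("<parallel_sets_model> n=%d  axes %s(k=%d) x %s(k=%d)  %d ribbons\n",
              x$n, x$axes[[1]]$modality, x$axes[[1]]$k,
              x$axes[[2]]$modality, x$axes[[2]]$k, nrow(x$ribbons)))
  invisible(x)
}

#' Compute parallel-sets layout geometry
#'
#' Assigns normalized vertical geometry in `[0, 1]`: per axis, blocks are
#' stacked top-to-bottom in canonical label order with uniform gaps and
#' heights proportional to patient counts; within each block, ribbon
#' stubs are stacked in opposite-axis label order (a stable convention),
#' with extent proportional to ribbon count.
#'
#' @param p A `parallel_sets_model` from [cross_tabulate].
#' @param gap Fraction of axis length used as spacing between consecutive
#'   blocks, in `[0, 0.5)`.
#' @return The model with `gap` set, a `height`/`y` column per block
#'   table, and `width`, `y_a`, `h_a`, `y_b`, `h_b` ribbon columns
#'   (`width` is the patient fraction `count / n`; `h_*` are the per-axis
#'   extents `width * usable_length`).
#' @export
layout_parallel_sets <- function(p, gap = 0.02) {
  if (gap < 0 || gap >= 0.5) stop("gap must be in [0, 0.5)")
  usable <- numeric(2)
  for (ax in 1:2) {
    k <- nrow(p$blocks[[ax]])
    usable[ax] <- 1 - gap * (k - 1)
    if (usable[ax] <= 0)
      stop("gap ", gap, " leaves no room for ", k, " blocks")
    h <- p$blocks[[ax]]$count / p$n * usable[ax]
    if (any(h <= 0)) stop("non-positive block height on axis ", ax)
    p$blocks[[ax]]$height <- h
    p$blocks[[ax]]$y <- cumsum(c(0, h[-k] + gap))
  }
  p$gap <- gap
  rb <- p$ribbons
  rb$width <- rb$count / p$n
  for (ax in 1:2) {
    own <- c("label_a", "label_b")[ax]
    other <- c("label_b", "label_a")[ax]
    ycol <- c("y_a", "y_b")[ax]
    hcol <- c("h_a", "h_b")[ax]
    rb[[hcol]] <- rb$width * usable[ax]
    rb[[ycol]] <- NA_real_
    for (l in p$blocks[[ax]]$label) {
      in_block <- which(rb[[own]] == l)
      in_block <- in_block[order(rb[[other]][in_block])]
      y0 <- p$blocks[[ax]]$y[p$blocks[[ax]]$label == l]
      rb[[ycol]][in_block] <- y0 + cumsum(c(0, rb[[hcol]][in_block]))[
        seq_along(in_block)]
    }
  }
  p$ribbons <- rb
  p
}

#' Resolve a subgroup selection from blocks and ribbons
#'
#' Batch equivalent of clicking blocks or ribbons in a parallel-sets
#' view: the subgroup's members are the union of the selected parts'
#' patient sets (overlapping parts de-duplicate silently).
#'
#' @param p A `parallel_sets_model`.
#' @param name Subgroup name (propagated to survival output).
#' @param blocks List (or n-by-2 matrix) of `(axis, label)` block
#'   references, axis in `{1, 2}`.
#' @param ribbons List (or n-by-2 matrix) of `(label_a, label_b)` ribbon
#'   references.
#' @return An object of class `subgroup_selection`: list with `name`,
#'   `member_ids`, `parts`.
#' @export
select_subgroup <- function(p, name, blocks = NULL, ribbons = NULL) {
  as_pairs <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
    x
  }
  blocks <- as_pairs(blocks)
  ribbons <- as_pairs(ribbons)
  if (length(blocks) == 0 && length(ribbons) == 0)
    stop("selection '", name, "' names no blocks or ribbons")
  members <- character(0)
  for (bl in blocks) {
    ax <- bl[[1]]; lab <- bl[[2]]
    if (!(ax %in% 1:2) || !(lab %in% p$blocks[[ax]]$label))
      stop("unknown block (", ax, ",", lab, ") in selection '", name, "'")
    assign_ax <- p$axes[[ax]]
    members <- c(members, assign_ax$sample_ids[assign_ax$labels == lab])
  }
  for (rb in ribbons) {
    hit <- which(p$ribbons$label_a == rb[[1]] & p$ribbons$label_b == rb[[2]])
    if (length(hit) != 1)
      stop("unknown ribbon (", rb[[1]], ",", rb[[2]], ") in selection '",
           name, "'")
    members <- c(members, p$ribbons$members[[hit]])
  }
  members <- unique(members)
  if (length(members) == 0) stop("selection '", name, "' resolves to no patients")
  structure(list(name = name, member_ids = members,
                 parts = list(blocks = blocks, ribbons = ribbons)),
            class = "subgroup_selection")
}

#' Complement of a subgroup within the cohort
#'
#' @param p A `parallel_sets_model`.
#' @param s A `subgroup_selection` over `p`'s cohort.
#' @param name Name for the complement subgroup.
#' @return A `subgroup_selection` containing every cohort member not in
#'   `s`; errors if the complement is empty.
#' @export
complement_subgroup <- function(p, s, name = paste0("not_", s$name)) {
  members <- setdiff(p$sample_ids, s$member_ids)
  if (length(members) == 0)
    stop("complement of '", s$name, "' is empty (selection covers the cohort)")
  structure(list(name = name, member_ids = members,
                 parts = list(complement_of = s$name)),
            class = "subgroup_selection")
}

#' Serialize a parallel-sets model to JSON
#'
#' Writes the rendering contract a front end would consume: axes
#' (modality, method, k), per-axis blocks (label, count, height, y),
#' ribbons (labels, count, width, geometry, optionally member IDs) and
#' the gap.
#'
#' @param p A laid-out `parallel_sets_model`.
#' @param path Output path.
#' @param include_members Write per-ribbon member sample IDs? Default
#'   `FALSE`.
#' @return `path`, invisibly.
#' @export
write_parallel_sets_json <- function(p, path, include_members = FALSE) {
  rb <- p$ribbons
  ribbons <- lapply(seq_len(nrow(rb)), function(r) {
    out <- list(label_a = rb$label_a[r], label_b = rb$label_b[r],
                count = rb$count[r])
    for (col in c("width", "y_a", "h_a", "y_b", "h_b"))
      if (!is.null(rb[[col]])) out[[col]] <- rb[[col]][r]
    if (include_members) out$members <- rb$members[[r]]
    out
  })
  obj <- list(
    n = p$n, gap = p$gap,
    axes = lapply(p$axes, function(a)
      list(modality = a$modality, method = a$method, k = a$k)),
    blocks = p$blocks,
    ribbons = ribbons)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
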