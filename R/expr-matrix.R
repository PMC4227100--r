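#' Expression matrix container
#'
#' A features-by-samples numeric matrix for one measurement modality
#' (e.g. `"mRNA"` or `"miRNA"`), with unique feature and sample identifiers.
#' All downstream operations (feature selection, preprocessing, clustering,
#' similarity graphs) consume this container.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param feature_ids Character vector of unique feature names (row ids).
#' @param sample_ids Character vector of unique sample names (column ids).
#' @param modality Short tag for the measurement type, e.g. `"mRNA"`.
#'
#' @return An object of class `expr_matrix`: a list with elements
#'   `modality`, `feature_ids`, `sample_ids` and `values` (the matrix
#'   carries the ids as dimnames).
#' @export
expr_matrix <- function(values, feature_ids = rownames(values),
                        sample_ids = colnames(values), modality = "expr") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(feature_ids))
    stop("values has ", nrow(values), " rows but ", length(feature_ids),
         " feature ids")
  if (ncol(values) != length(sample_ids))
    stop("values has ", ncol(values), " columns but ", length(sample_ids),
         " sample ids")
  if (anyDuplicated(feature_ids))
    stop("duplicated feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(values))
    stop("expression matrix contains missing values")
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(modality = as.character(modality)[1],
                 feature_ids = feature_ids,
                 sample_ids = sample_ids,
                 values = values),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> modality=%s  %d features x %d samples\n",
              x$modality, length(x$feature_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Restrict an expr_matrix to a subset/permutation of its samples.
subset_samples <- function(m, sample_ids) {
  expr_matrix(m$values[, sample_ids, drop = FALSE],
              feature_ids = m$feature_ids,
              sample_ids = sample_ids,
              modality = m$modality)
}
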