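#' Preprocess an expression matrix
#'
#' Optional log transform and per-feature standardization, applied in that
#' order. The log transform is `log2(x + 1)` and requires non-negative
#' input. Z-scoring centers each feature row to mean 0 and scales it to
#' standard deviation 1 using the population (divide-by-n) formula; rows
#' with zero variance are set to all zeros with a warning.
#'
#' @param m An [expr_matrix].
#' @param log_transform Apply `log2(x + 1)`? Default `FALSE`.
#' @param normalize `"zscore"` or `"none"`.
#' @return A preprocessed [expr_matrix].
#' @export
preprocess <- function(m, log_transform = FALSE,
                       normalize = c("none", "zscore")) {
  normalize <- match.arg(normalize)
  v <- m$values
  if (log_transform) {
    neg <- which(rowSums(v < 0) > 0)
    if (length(neg))
      stop("negative values preclude log transform; first offending feature: ",
           m$feature_ids[neg[1]])
    v <- log2(v + 1)
  }
  if (normalize == "zscore") {
    mu <- rowMeans(v)
    sd_pop <- sqrt(rowMeans((v - mu)^2))
    flat <- sd_pop == 0
    if (any(flat)) {
      warning(sum(flat), " zero-variance feature row(s) set to all zeros")
      sd_pop[flat] <- 1
    }
    v <- (v - mu) / sd_pop
    v[flat, ] <- 0
  }
  expr_matrix(v, feature_ids = m$feature_ids, sample_ids = m$sample_ids,
              modality = m$modality)
}

#' Restrict a matrix to a selected feature list
#'
#' Keeps only the features named in `fl`, in list order. Names absent from
#' the matrix are reported with a warning but do not abort; an empty
#' intersection is an error.
#'
#' @param m An [expr_matrix].
#' @param fl A `feature_list` from [load_feature_list], or a character
#'   vector of feature names.
#' @return The restricted [expr_matrix].
#' @export
select_features <- function(m, fl) {
  names <- if (inherits(fl, "feature_list")) fl$names else as.character(fl)
  hit <- names[names %in% m$feature_ids]
  miss <- setdiff(names, m$feature_ids)
  if (length(hit) == 0)
    stop("no selected features found in the matrix; unmatched: ",
         paste(miss, collapse = ", "))
  if (length(miss))
    warning(length(miss), " selected feature(s) not in the matrix: ",
            paste(miss, collapse = ", "))
  expr_matrix(m$values[hit, , drop = FALSE], feature_ids = hit,
              sample_ids = m$sample_ids, modality = m$modality)
}
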