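#' Load an expression matrix from delimited text
#'
#' Reads a features-by-samples table: first row holds sample IDs, first
#' column holds feature names, remaining cells are numeric expression
#' values. The delimiter is auto-detected (tab vs comma) unless given.
#' Duplicated feature rows are collapsed by their mean (a common
#' microarray convention) with a message; rows containing missing cells
#' are dropped with a warning rather than imputed.
#'
#' @param path Path to a TSV/CSV file.
#' @param modality Modality tag to attach, e.g. `"mRNA"`.
#' @param delimiter `"auto"` (default), `"\t"` or `","`.
#'
#' @return An [expr_matrix].
#' @export
load_expression <- function(path, modality = "expr", delimiter = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("empty or header-only expression file: ", path)

  if (identical(delimiter, "auto")) {
    count <- function(ch) sum(gregexpr(ch, lines[1], fixed = TRUE)[[1]] > 0)
    delimiter <- if (count("\t") >= count(",")) "\t" else ","
  }
  # keep trailing empty fields (missing cells) that strsplit would drop
  split1 <- function(x) trimws(strsplit(paste0(x, delimiter),
                                        delimiter, fixed = TRUE)[[1]])
  header <- split1(lines[1])
  body <- lapply(lines[-1], split1)
  widths <- lengths(body)
  if (length(unique(widths)) != 1)
    stop("ragged rows in ", path, ": widths ", paste(unique(widths), collapse = ", "))
  w <- widths[1]

  # Header may or may not carry a label over the feature-name column.
  if (length(header) == w) {
    sample_ids <- header[-1]
  } else if (length(header) == w - 1L) {
    sample_ids <- header
  } else {
    stop("cannot orient ", path, ": header has ", length(header),
         " fields but data rows have ", w)
  }
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ID in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))

  feature_ids <- vapply(body, `[`, character(1), 1L)
  cells <- t(vapply(body, function(r) r[-1L], character(w - 1L)))
  if (w == 2L) cells <- matrix(vapply(body, `[`, character(1), 2L), ncol = 1L)

  missing_mask <- cells == "" | toupper(cells) == "NA"
  suppressWarnings(num <- array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !missing_mask, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s' in %s",
                 cells[bad[1, 1], bad[1, 2]], feature_ids[bad[1, 1]],
                 sample_ids[bad[1, 2]], path))

  drop_rows <- rowSums(missing_mask) > 0
  if (any(drop_rows)) {
    warning(sum(drop_rows), " feature row(s) with missing values dropped")
    num <- num[!drop_rows, , drop = FALSE]
    feature_ids <- feature_ids[!drop_rows]
  }
  if (nrow(num) == 0) stop("no complete feature rows left in ", path)

  if (anyDuplicated(feature_ids)) {
    dups <- unique(feature_ids[duplicated(feature_ids)])
    message("collapsing ", length(dups), " duplicated feature id(s) by mean")
    num <- rowsum(num, group = feature_ids, reorder = FALSE) /
      as.vector(table(factor(feature_ids, levels = unique(feature_ids))))
    feature_ids <- unique(feature_ids)
  }
  expr_matrix(num, feature_ids = feature_ids, sample_ids = sample_ids,
              modality = modality)
}

#' Write an expression matrix to tab-separated text
#'
#' Inverse of [load_expression]; values are written with 10 significant
#' digits so a round trip reproduces them to within 1e-9 relative error.
#'
#' @param m An [expr_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", m$sample_ids), collapse = "\t"), con)
  body <- vapply(seq_along(m$feature_ids), function(i) {
    paste(c(m$feature_ids[i], sprintf("%.10g", m$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Load a clinical table
#'
#' Reads a CSV with one row per sample. Required columns (names
#' configurable through `columns`): sample ID, survival time and event
#' status; `age` and `tumor_grade` are kept when present. Event status
#' must be codable as 0 (censored) / 1 (event); survival times must be
#' non-negative. Rows missing time or status are dropped with a message.
#'
#' @param path CSV path.
#' @param columns Named list mapping the canonical names `sample_id`,
#'   `survival_time`, `event_status` (optionally `age`, `tumor_grade`)
#'   to the column names used in the file.
#'
#' @return A `data.frame` of class `clinical_table` with canonical column
#'   names.
#' @export
load_clinical <- function(path,
                          columns = list(sample_id = "sample_id",
                                         survival_time = "survival_time",
                                         event_status = "event_status",
                                         age = "age",
                                         tumor_grade = "tumor_grade")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "survival_time", "event_status")
  for (nm in req) if (is.null(columns[[nm]])) columns[[nm]] <- nm
  missing_cols <- req[!vapply(req, function(nm) columns[[nm]] %in% names(raw),
                              logical(1))]
  if (length(missing_cols))
    stop("clinical table is missing required column(s): ",
         paste(vapply(missing_cols, function(nm) columns[[nm]], character(1)),
               collapse = ", "),
         " (expected names for: ", paste(missing_cols, collapse = ", "), ")")

  out <- data.frame(sample_id = as.character(raw[[columns$sample_id]]),
                    survival_time = suppressWarnings(
                      as.numeric(raw[[columns$survival_time]])),
                    event_status = suppressWarnings(
                      as.numeric(raw[[columns$event_status]])),
                    stringsAsFactors = FALSE)
  for (opt in c("age", "tumor_grade")) {
    cn <- columns[[opt]]
    if (!is.null(cn) && cn %in% names(raw)) out[[opt]] <- raw[[cn]]
  }

  drop <- is.na(out$survival_time) | is.na(raw[[columns$event_status]]) |
    (is.character(raw[[columns$event_status]]) &
       !nzchar(trimws(raw[[columns$event_status]])))
  bad_status <- !is.na(out$event_status) & !(out$event_status %in% c(0, 1))
  if (any(bad_status))
    stop("event_status values outside {0,1}: ",
         paste(unique(out$event_status[bad_status]), collapse = ", "))
  if (any(is.na(out$event_status) & !drop))
    stop("event_status not coercible to {0,1}")
  if (any(drop)) {
    message("dropping ", sum(drop), " clinical row(s) with missing time/status")
    out <- out[!drop, , drop = FALSE]
  }
  if (nrow(out) == 0) stop("no usable clinical rows in ", path)
  if (any(out$survival_time < 0))
    stop("negative survival_time for sample(s): ",
         paste(out$sample_id[out$survival_time < 0], collapse = ", "))
  if (anyDuplicated(out$sample_id))
    stop("duplicated sample_id in clinical table: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "))
  rownames(out) <- NULL
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Load a comma-delimited feature list
#'
#' Parses a plain-text, comma-delimited list of feature names (whitespace
#' and newlines around names are tolerated). Duplicates are removed with a
#' warning, preserving first-occurrence order.
#'
#' @param path Path to the list file.
#' @param modality Modality tag the list applies to.
#' @return An object of class `feature_list`: list with `modality`, `names`.
#' @export
load_feature_list <- function(path, modality = "expr") {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = ",")
  names <- trimws(strsplit(txt, ",", fixed = TRUE)[[1]])
  names <- names[nzchar(names)]
  if (length(names) == 0) stop("feature list is empty after parsing: ", path)
  if (anyDuplicated(names)) {
    warning("dropping ", sum(duplicated(names)),
            " duplicated feature list entrie(s)")
    names <- unique(names)
  }
  structure(list(modality = modality, names = names), class = "feature_list")
}

#' Align two modalities and the clinical table to shared samples
#'
#' Restricts both expression matrices and the clinical table to the
#' intersection of their sample IDs, in the order the samples appear in
#' the first matrix, so all three outputs share one identical sample
#' sequence.
#'
#' @param a,b [expr_matrix] objects for the two modalities.
#' @param clin A `clinical_table` from [load_clinical].
#' @return List with elements `a`, `b`, `clin`, all restricted and ordered
#'   identically.
#' @export
align_modalities <- function(a, b, clin) {
  shared <- a$sample_ids[a$sample_ids %in% b$sample_ids &
                           a$sample_ids %in% clin$sample_id]
  if (length(shared) == 0)
    stop("no samples shared between the two modalities and the clinical table")
  message("aligned cohort: ", length(shared), " shared samples")
  clin2 <- clin[match(shared, clin$sample_id), , drop = FALSE]
  rownames(clin2) <- NULL
  list(a = subset_samples(a, shared),
       b = subset_samples(b, shared),
       clin = clin2)
}

#' Write a clinical table to CSV
#' @param clin A `clinical_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clin, path) {
  df <- as.data.frame(clin)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
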