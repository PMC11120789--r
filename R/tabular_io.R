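# Reading, validating and writing the tabular formats the package consumes:
# feature tables (samples x features), study designs, square distance matrices
# and result tables. TSV is the default; CSV is recognised by file extension.

.sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Validate a feature table
#'
#' A feature table is a numeric matrix with unique sample IDs as row names and
#' unique feature IDs as column names. Abundance tables must be non-negative;
#' real-valued tables (e.g. CLR-transformed data or simulated coordinates) are
#' accepted where `allow_negative = TRUE`.
#'
#' @param x numeric matrix with dimnames.
#' @param allow_negative logical; permit negative values (default `FALSE`).
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_feature_table <- function(x, allow_negative = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("feature table must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("feature table must carry sample IDs (rownames) and feature IDs (colnames)")
  if (anyDuplicated(rownames(x)))
    stop("duplicated sample IDs: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicated feature IDs: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(!is.finite(x)))
    stop("feature table contains non-finite values")
  if (!allow_negative && any(x < 0)) {
    idx <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at sample '%s', feature '%s'",
                 rownames(x)[idx[1L]], colnames(x)[idx[2L]]))
  }
  invisible(x)
}

#' Read a feature abundance table
#'
#' Reads a delimited text file with one ID header row and one ID column into a
#' samples-by-features numeric matrix. Orientation is declared, not guessed:
#' files with features in rows are transposed on read.
#'
#' @param path file path (TSV by default; `.csv` files are comma-separated).
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`.
#' @param allow_negative logical; accept negative values (for real-valued
#'   coordinate tables such as simulator output).
#' @return numeric matrix, samples in rows, validated.
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_in_rows", "features_in_rows"),
                               allow_negative = FALSE) {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L)
    stop("expected an ID column followed by at least one data column in ", path)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- raw[, -1L, drop = FALSE]
  mat <- matrix(NA_real_, nrow(body), ncol(body),
                dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    col <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(col) & !is.na(body[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                   body[bad[1L], j], ids[bad[1L]], colnames(body)[j], path))
    mat[, j] <- col
  }
  if (orientation == "features_in_rows") mat <- t(mat)
  validate_feature_table(mat, allow_negative = allow_negative)
  mat
}

#' Read a study design table
#'
#' The design file links samples to subjects and observation times. Required
#' columns: `sample`, `subject`, `time`; optional: `group`.
#'
#' @param path file path (TSV default, CSV by extension).
#' @return data.frame with columns `sample`, `subject`, `time` and, when
#'   present in the file, `group`.
#' @export
read_design <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  for (col in c("sample", "subject", "time"))
    if (!col %in% names(df))
      stop("design file ", path, " lacks required column '", col, "'")
  df$sample <- as.character(df$sample)
  df$subject <- as.character(df$subject)
  df$time <- suppressWarnings(as.numeric(df$time))
  if (anyNA(df$time)) stop("non-numeric values in 'time' column of ", path)
  if (any(df$time < 0)) stop("negative times in ", path)
  if (anyDuplicated(df$sample))
    stop("duplicated sample IDs in design: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  keep <- c("sample", "subject", "time", if ("group" %in% names(df)) "group")
  df <- df[, keep, drop = FALSE]
  if ("group" %in% names(df)) df$group <- as.character(df$group)
  df
}

#' Drop low-sum samples from a feature table
#'
#' Keeps exactly the samples whose row sum is at least `threshold`; the feature
#' set is unchanged. The threshold applies to the table on whatever scale it is
#' in (no rescaling is performed first); for relative-abundance tables a
#' threshold of 0.8 removes badly undersampled profiles.
#'
#' @param table feature table matrix (samples in rows).
#' @param threshold non-negative row-sum cutoff.
#' @return the filtered table; the number of dropped samples is reported via
#'   `message()` and attached as attribute `"n_dropped"`.
#' @export
filter_samples_by_sum <- function(table, threshold) {
  validate_feature_table(table, allow_negative = TRUE)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("threshold must be a single non-negative number")
  keep <- rowSums(table) >= threshold
  if (!any(keep))
    stop("threshold ", threshold, " removes every sample")
  out <- table[keep, , drop = FALSE]
  n_dropped <- sum(!keep)
  message(n_dropped, " sample(s) dropped by row-sum filter (threshold ",
          threshold, "); ", nrow(out), " retained")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a result table
#'
#' Writes a non-empty data.frame or matrix as delimited text with a header,
#' full numeric precision and deterministic row order (rows are written as
#' given). Matrices with row names gain a leading `id` column so that reading
#' the file back recovers the names.
#'
#' @param records data.frame or matrix with at least one row.
#' @param path output path (TSV default, CSV by extension).
#' @return invisibly, `path`.
#' @export
write_table <- function(records, path) {
  if (is.null(records) || NROW(records) == 0L)
    stop("refusing to write an empty table")
  sep <- .sniff_sep(path)
  if (is.matrix(records)) {
    df <- as.data.frame(records, stringsAsFactors = FALSE)
    if (!is.null(rownames(records)))
      df <- cbind(id = rownames(records), df, stringsAsFactors = FALSE)
    records <- df
  }
  utils::write.table(format(records, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Validate a distance matrix
#'
#' @param d square numeric matrix with matching row/column IDs; must be
#'   symmetric within 1e-9, have an exactly zero diagonal and no negative
#'   entries.
#' @return `d`, invisibly.
#' @export
validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    stop("distance matrix must be a square numeric matrix")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    stop("distance matrix must carry IDs as dimnames")
  if (!identical(rownames(d), colnames(d)))
    stop("distance matrix row and column IDs disagree")
  if (anyDuplicated(rownames(d)))
    stop("duplicated IDs in distance matrix")
  if (any(!is.finite(d))) stop("distance matrix contains non-finite values")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric (tolerance 1e-9)")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be exactly zero")
  if (any(d < 0)) stop("distance matrix contains negative entries")
  invisible(d)
}

#' Read a square distance matrix
#'
#' Expects the full square layout: an ID header row and an ID first column.
#' Tiny diagonal round-off (below 1e-12) is snapped to exact zero.
#'
#' @param path file path.
#' @return validated square numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  m <- read_feature_table(path, allow_negative = TRUE)
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal must be zero")
  diag(m) <- 0
  validate_distance_matrix(m)
  m
}

#' Write a square distance matrix
#'
#' @param d validated distance matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_distance_matrix <- function(d, path) {
  validate_distance_matrix(d)
  write_table(d, path)
}
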