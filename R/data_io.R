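# Reading and writing expression matrices, label files and score tables,
# plus the zero-expression preprocessing filter.

#' Read an expression matrix from delimited text
#'
#' Reads a TSV/CSV file with one header row and one identifier column and
#' returns a numeric matrix in the canonical features x samples
#' orientation. Files stored samples-in-rows are transposed on load so the
#' in-memory representation is always the same.
#'
#' @param path path to a delimited text file.
#' @param orientation `"features_in_rows"` (default) if rows are
#'   features/genes, `"samples_in_rows"` if rows are samples.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @return numeric matrix, features x samples, with feature ids as
#'   `rownames` and sample ids as `colnames`.
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' write.table(data.frame(feature_id = rownames(m), m),
#'             tmp, sep = "\t", quote = FALSE, row.names = FALSE)
#' X <- read_expression_matrix(tmp)
#' dim(X)
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("features_in_rows",
                                                   "samples_in_rows"),
                                   sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      quote = "", comment.char = "",
                      stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(df) < 2L)
    stop("expected an id column plus at least one data column in ", path,
         call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  raw <- as.matrix(df[, -1L, drop = FALSE])
  rownames(raw) <- ids
  if (!is.numeric(raw)) {
    num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw),
                                  dimnames = dimnames(raw)))
    bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                   raw[bad[1L, 1L], bad[1L, 2L]],
                   rownames(raw)[bad[1L, 1L]],
                   colnames(raw)[bad[1L, 2L]], path), call. = FALSE)
    raw <- num
  }
  if (anyNA(raw))
    stop("missing values in ", path,
         "; the loader rejects incomplete matrices", call. = FALSE)
  X <- if (orientation == "samples_in_rows") t(raw) else raw
  validate_expression_matrix(X)
  X
}

#' Read per-sample class labels
#'
#' Reads a two-column delimited file (`sample_id`, `label`) and returns a
#' factor aligned to the sample order of a paired expression matrix.
#'
#' @param path path to the label file.
#' @param sample_ids character vector of sample ids to align to (usually
#'   `colnames(X)`).
#' @param sep field separator, `"\t"` by default.
#' @return factor of length `length(sample_ids)` named by sample id.
#' @export
read_labels <- function(path, sample_ids, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("label file must have columns sample_id and label", call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in label file", call. = FALSE)
  missing <- setdiff(sample_ids, ids)
  if (length(missing))
    stop("label file is missing sample(s): ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  lab <- as.character(df[[2L]])[match(sample_ids, ids)]
  stats::setNames(factor(lab, levels = unique(lab)), sample_ids)
}

#' Filter features by zero-expression fraction
#'
#' Removes features whose fraction of zero entries across all samples
#' exceeds `max_zero_fraction` (strictly); the standard preprocessing step
#' for sparse expression data. A feature is kept iff its zero fraction is
#' `<=` the threshold. Surviving features keep their original order.
#'
#' @param X expression matrix (features x samples).
#' @param max_zero_fraction maximum tolerated fraction of zeros, default
#'   0.25.
#' @param zero_tol entries with absolute value `<= zero_tol` count as
#'   zero; default 0 (exact zeros only).
#' @return the filtered matrix.
#' @export
filter_zero_fraction <- function(X, max_zero_fraction = 0.25, zero_tol = 0) {
  validate_expression_matrix(X)
  stopifnot(is.numeric(max_zero_fraction), length(max_zero_fraction) == 1L,
            max_zero_fraction >= 0, max_zero_fraction <= 1)
  zero_frac <- rowMeans(abs(X) <= zero_tol)
  keep <- zero_frac <= max_zero_fraction
  if (!any(keep))
    stop("all features exceed the zero-fraction threshold (",
         max_zero_fraction, "); raise max_zero_fraction", call. = FALSE)
  X[keep, , drop = FALSE]
}

#' Write a feature score table to TSV
#'
#' Writes columns `feature_id`, `score`, `rank` in rank order (rank 1 =
#' highest score, ties broken lexicographically). Scores are printed with
#' 15 significant digits so a read-back reproduces them.
#'
#' @param tbl a `feature_score_table` from [score_table()] or a scoring
#'   function.
#' @param path output file path.
#' @export
write_score_table <- function(tbl, path) {
  stopifnot(all(c("feature_id", "score", "rank") %in% names(tbl)))
  tbl <- tbl[order(tbl$rank), c("feature_id", "score", "rank")]
  out <- data.frame(feature_id = tbl$feature_id,
                    score = sprintf("%.15g", tbl$score),
                    rank = tbl$rank, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("could not write score table to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a feature score table written by [write_score_table()]
#'
#' @param path path to the TSV file.
#' @return a `feature_score_table`.
#' @export
read_score_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("feature_id", "score", "rank") %in% names(df)))
  tbl <- df[order(df$rank), c("feature_id", "score", "rank")]
  rownames(tbl) <- NULL
  class(tbl) <- c("feature_score_table", "data.frame")
  tbl
}
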