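# Internal validators and shared small helpers.

#' Validate an expression matrix
#'
#' Checks the canonical container contract: a numeric matrix, at least one
#' feature and two samples, unique feature and sample identifiers, and no
#' missing values.
#'
#' @param X numeric matrix, features x samples, with `rownames` (feature
#'   ids) and `colnames` (sample ids).
#' @return `X`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(X) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (nrow(X) < 1L)
    stop("expression matrix must have at least one feature", call. = FALSE)
  if (ncol(X) < 2L)
    stop("expression matrix must have at least two samples", call. = FALSE)
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("expression matrix must carry feature ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  if (anyDuplicated(rownames(X)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(X)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(X))
    stop("expression matrix contains missing values; impute or drop before scoring",
         call. = FALSE)
  invisible(X)
}

# Coerce labels to a factor paired with X and check class sizes.
as_label_vector <- function(y, X, min_per_class = 2L) {
  if (length(y) != ncol(X))
    stop("label vector length (", length(y), ") does not match sample count (",
         ncol(X), ")", call. = FALSE)
  y <- if (is.factor(y)) droplevels(y) else factor(y, levels = unique(as.character(y)))
  if (nlevels(y) < 2L)
    stop("need at least two classes, got ", nlevels(y), call. = FALSE)
  sizes <- table(y)
  small <- names(sizes)[sizes < min_per_class]
  if (length(small))
    stop("class(es) with fewer than ", min_per_class, " samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  y
}

# Deterministic ordering used for all rankings: descending score, ties
# broken by feature id in C-locale lexicographic order.
score_order <- function(scores, feature_ids) {
  order(-scores, feature_ids, method = "radix")
}

#' Build a feature score table
#'
#' Assembles the per-feature score container: a data frame with columns
#' `feature_id`, `score` and `rank`, sorted by rank (rank 1 = highest
#' score; ties broken lexicographically by feature id).
#'
#' @param feature_ids character vector of unique feature identifiers.
#' @param scores numeric vector of signed scores, same length.
#' @return a `feature_score_table` (data frame) ordered by rank.
#' @export
score_table <- function(feature_ids, scores) {
  stopifnot(length(feature_ids) == length(scores))
  if (any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  ord <- score_order(scores, feature_ids)
  tbl <- data.frame(feature_id = as.character(feature_ids)[ord],
                    score = as.numeric(scores)[ord],
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(tbl) <- NULL
  class(tbl) <- c("feature_score_table", "data.frame")
  tbl
}

# Derive a child RNG seed from a master seed; kept well below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
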