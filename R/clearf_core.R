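# Core ClearF scoring: class-wise embedding and reconstruction-error
# differencing.

#' Partition samples by class
#'
#' Splits the sample columns of `X` into one block per class. Within each
#' block the original sample order is preserved.
#'
#' @param X expression matrix (features x samples).
#' @param y class labels, one per sample (factor or coercible).
#' @return list of class `class_partition` with elements `indices` (list
#'   of integer column indices per class) and `classes` (class labels, in
#'   order of first appearance for non-factor input).
#' @export
partition_by_class <- function(X, y) {
  validate_expression_matrix(X)
  y <- as_label_vector(y, X)
  idx <- split(seq_len(ncol(X)), y)
  structure(list(indices = idx, classes = names(idx)),
            class = "class_partition")
}

#' ClearF feature scores
#'
#' Scores every feature as \eqn{F = R_X - \sum_j R_j}: the feature-wise
#' reconstruction error of a low-dimensional embedding fitted to all
#' samples, minus the summed errors of embeddings refitted independently
#' on each class block. Features that are compactly explained within
#' classes but not across the pooled data -- i.e. features whose
#' distribution shifts with the class -- receive high scores.
#'
#' The embedder is refitted from scratch on every class block; whole-data
#' loadings are never reused. The requested number of components applies
#' to the whole-data fit, and is clipped per block (with a warning) when a
#' class has too few samples to support it.
#'
#' @param X expression matrix (features x samples).
#' @param y class labels, one per sample; every class needs >= 2 samples.
#'   Two or more classes are supported.
#' @param cfg an [embedder_config()].
#' @param keep_components if `TRUE`, attach the intermediate error vectors
#'   (`r_x` and the per-class list `r_class`) as the `"components"`
#'   attribute for diagnostics.
#' @return a `feature_score_table`: data frame with `feature_id`, `score`,
#'   `rank`, sorted by rank (descending score, lexicographic ties).
#' @seealso [clearf_one_scores()], [clearfpp_scores()]
#' @export
clearf_scores <- function(X, y, cfg = embedder_config(),
                          keep_components = FALSE) {
  validate_expression_matrix(X)
  y <- as_label_vector(y, X)
  part <- partition_by_class(X, y)

  r_x <- reconstruction_error_for(X, cfg)
  r_class <- lapply(part$indices, function(idx)
    reconstruction_error_for(X[, idx, drop = FALSE], cfg))
  r_sum <- Reduce(`+`, r_class)
  f <- r_x - r_sum

  tbl <- score_table(rownames(X), f)
  if (isTRUE(keep_components))
    attr(tbl, "components") <- list(r_x = r_x, r_class = r_class,
                                    r_sum = r_sum)
  attr(tbl, "method") <- if (cfg$n_components == 1L) "clearf-one" else "clearf"
  attr(tbl, "embedder") <- cfg
  tbl
}

#' ClearF-one feature scores
#'
#' The single-component specialization of [clearf_scores()]: the embedding
#' bottleneck is fixed at one dimension, which removes the need to search
#' over bottleneck sizes and concentrates the score on the strongest
#' per-class signal.
#'
#' @inheritParams clearf_scores
#' @return a `feature_score_table`, identical to
#'   `clearf_scores(X, y, cfg with n_components = 1)`.
#' @export
clearf_one_scores <- function(X, y, cfg = embedder_config(),
                              keep_components = FALSE) {
  cfg$n_components <- 1L
  clearf_scores(X, y, cfg, keep_components = keep_components)
}
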