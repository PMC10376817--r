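# ClearF++ orchestration: cluster features, score each cluster with the
# one-component method, merge into a single ranking; plus cross-fold rank
# aggregation.

#' ClearF++ configuration
#'
#' @param clustering_method `"dec"` (default) or `"kmeans"`.
#' @param k number of feature clusters. Defaults to 15 for DEC and 5 for
#'   k-means (the best-performing counts for each method).
#' @param embedder an [embedder_config()]; `n_components` is forced to 1
#'   (ClearF++ always uses the one-component score within clusters).
#' @param score_normalization how per-cluster scores are put on a common
#'   scale before merging: `"none"` (default, raw scores concatenated),
#'   `"zscore_per_cluster"`, or `"rank_per_cluster"` (descending rank
#'   points scaled to (0, 1]).
#' @param seed master seed fanned out to clustering; recorded in the
#'   output.
#' @param dec a [dec_config()] used when `clustering_method = "dec"`.
#' @param cluster_scale passed to the clustering method; `"profile"`
#'   (default) or `"none"`.
#' @return list of class `clearfpp_config`.
#' @export
clearfpp_config <- function(clustering_method = c("dec", "kmeans"),
                            k = NULL,
                            embedder = embedder_config(),
                            score_normalization = c("none",
                                                    "zscore_per_cluster",
                                                    "rank_per_cluster"),
                            seed = 1L,
                            dec = dec_config(),
                            cluster_scale = c("profile", "none")) {
  clustering_method <- match.arg(clustering_method)
  score_normalization <- match.arg(score_normalization)
  cluster_scale <- match.arg(cluster_scale)
  if (is.null(k)) k <- if (clustering_method == "dec") 15L else 5L
  stopifnot(k >= 1L)
  embedder$n_components <- 1L
  structure(list(clustering_method = clustering_method,
                 k = as.integer(k),
                 embedder = embedder,
                 score_normalization = score_normalization,
                 seed = as.integer(seed),
                 dec = dec,
                 cluster_scale = cluster_scale),
            class = "clearfpp_config")
}

normalize_cluster_scores <- function(f, how) {
  if (how == "none" || length(f) == 1L) {
    if (how == "zscore_per_cluster" && length(f) == 1L) return(f * 0)
    return(f)
  }
  if (how == "zscore_per_cluster") {
    s <- stats::sd(f)
    if (!is.finite(s) || s == 0) return(f * 0)
    return((f - mean(f)) / s)
  }
  # rank_per_cluster: best feature in a cluster gets 1, worst gets 1/size
  r <- rank(-f, ties.method = "min")
  (length(f) - r + 1) / length(f)
}

#' ClearF++ feature scores
#'
#' Partitions features into `k` clusters (k-means or DEC), runs the
#' one-component score ([clearf_one_scores()]) independently within each
#' cluster against the same labels, and merges the per-cluster score
#' vectors back to a single ranking. Each feature is scored exactly once,
#' from the cluster it belongs to. With `k = 1` the result reduces
#' exactly to [clearf_one_scores()] on the full matrix.
#'
#' A singleton cluster (one feature) scores 0: one-dimensional data is
#' reconstructed exactly by a single component, so such features carry no
#' differential signal and never rank highly.
#'
#' @param X expression matrix (features x samples).
#' @param y class labels (every class >= 2 samples).
#' @param cfg a [clearfpp_config()].
#' @return a `feature_score_table` with attributes `assignment` (the
#'   `cluster_assignment` used) and `method = "clearfpp"`.
#' @export
clearfpp_scores <- function(X, y, cfg = clearfpp_config()) {
  validate_expression_matrix(X)
  stopifnot(inherits(cfg, "clearfpp_config"))
  y <- as_label_vector(y, X)
  cfg$embedder$n_components <- 1L

  if (cfg$k == 1L) {
    A <- cluster_assignment(
      stats::setNames(rep(1L, nrow(X)), rownames(X)), 1L,
      cfg$clustering_method, cfg$seed)
  } else if (cfg$clustering_method == "kmeans") {
    A <- kmeans_features(X, cfg$k, seed = cfg$seed,
                         scale = cfg$cluster_scale)
  } else {
    A <- dec_features(X, cfg$k, cfg = cfg$dec, seed = cfg$seed,
                      scale = cfg$cluster_scale)
  }

  blocks <- split_by_cluster(X, A)
  scores <- stats::setNames(rep(NA_real_, nrow(X)), rownames(X))
  for (blk in blocks) {
    if (nrow(blk) == 1L) {
      f <- stats::setNames(0, rownames(blk))
    } else {
      tb <- clearf_one_scores(blk, y, cfg$embedder)
      f <- stats::setNames(tb$score, tb$feature_id)[rownames(blk)]
    }
    scores[names(f)] <- normalize_cluster_scores(f,
                                                 cfg$score_normalization)
  }
  stopifnot(!anyNA(scores))

  tbl <- score_table(names(scores), unname(scores))
  attr(tbl, "method") <- "clearfpp"
  attr(tbl, "assignment") <- A
  attr(tbl, "config") <- cfg
  tbl
}

#' Select the top-ranked features
#'
#' @param tbl a `feature_score_table`.
#' @param m number of features to select, `1 <= m <= nrow(tbl)`.
#' @return character vector of `m` feature ids in descending score order
#'   (ties broken lexicographically, as in the table's ranking).
#' @export
select_top <- function(tbl, m) {
  stopifnot(all(c("feature_id", "rank") %in% names(tbl)))
  m <- as.integer(m)
  if (m < 1L || m > nrow(tbl))
    stop("m must be between 1 and ", nrow(tbl), call. = FALSE)
  tbl$feature_id[order(tbl$rank)][seq_len(m)]
}

#' Aggregate feature rankings across folds
#'
#' Consensus ranking over per-fold score tables: in each fold the rank-r
#' feature (r = 1..`top_m`) receives `top_m - r + 1` points and all other
#' features receive 0; the aggregate is the arithmetic mean of points over
#' folds. With the default `top_m = 100`, a feature ranked first in every
#' fold scores 100.
#'
#' @param tables list of `feature_score_table`s over the same feature
#'   universe (e.g. one per cross-validation fold).
#' @param top_m number of ranks that receive points per fold, default 100.
#' @return data frame of class `fold_rank_aggregate` with columns
#'   `feature_id` and `rank_score`, sorted by descending `rank_score`
#'   (ties lexicographic); attributes `n_folds` and `top_m`.
#' @export
aggregate_fold_ranks <- function(tables, top_m = 100L) {
  stopifnot(length(tables) >= 1L, top_m >= 1L)
  universe <- sort(tables[[1L]]$feature_id)
  for (tb in tables) {
    if (!identical(sort(tb$feature_id), universe))
      stop("score tables do not share the same feature universe",
           call. = FALSE)
  }
  pts <- vapply(tables, function(tb) {
    p <- pmax(top_m - tb$rank + 1L, 0L)
    stats::setNames(as.numeric(p), tb$feature_id)[universe]
  }, numeric(length(universe)))
  agg <- rowMeans(as.matrix(pts))
  ord <- score_order(agg, universe)
  out <- data.frame(feature_id = universe[ord],
                    rank_score = unname(agg[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "n_folds") <- length(tables)
  attr(out, "top_m") <- as.integer(top_m)
  class(out) <- c("fold_rank_aggregate", "data.frame")
  out
}
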