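pca_pp <- function(k, method = "kmeans", seed = 1L)
  clearfpp_config(clustering_method = method, k = k,
                  embedder = embedder_config(method = "pca",
                                             standardize = FALSE),
                  seed = seed)

test_that("a single cluster reduces bitwise to the one-component score", {
  for (seed in 1:5) {
    X <- rand_expr(25, 20, seed = seed)
    y <- half_labels(X)
    a <- clearfpp_scores(X, y, pca_pp(1))
    b <- clearf_one_scores(X, y, embedder_config(method = "pca",
                                                 standardize = FALSE))
    expect_identical(a$score, b$score)
    expect_identical(a$feature_id, b$feature_id)
  }
})

test_that("every feature is scored exactly once from its own cluster", {
  d <- generate_expression(synthetic_spec(n_features = 90, n_samples = 40,
                                          seed = 2))
  tb <- clearfpp_scores(d$X, d$y, pca_pp(4))
  expect_setequal(tb$feature_id, rownames(d$X))
  expect_identical(anyDuplicated(tb$feature_id), 0L)

  # per-cluster scores equal an independent per-cluster oracle run
  A <- attr(tb, "assignment")
  got <- setNames(tb$score, tb$feature_id)
  for (blk in split_by_cluster(d$X, A)) {
    if (nrow(blk) == 1L) {
      expect_identical(unname(got[rownames(blk)]), 0)
    } else {
      ref <- clearf_one_scores(blk, d$y,
                               embedder_config(method = "pca",
                                               standardize = FALSE))
      expect_identical(unname(got[ref$feature_id]), ref$score)
    }
  }
})

test_that("planted features in different clusters both reach the global top", {
  # two raw-profile clusters, each driven by a shared per-sample factor
  # (which the one-component embedding captures), plus one planted
  # class-shifted feature per cluster whose shift is orthogonal to the
  # factor and so survives as global reconstruction error
  withr::with_seed(77, {
    s <- 40
    cls <- rep(c(0, 1), each = s / 2)
    fac1 <- rnorm(s); fac2 <- rnorm(s)
    X <- rbind(5 + outer(rep(1, 20), fac1) +
                 matrix(rnorm(20 * s, sd = 0.3), 20, s),
               -5 + outer(rep(1, 20), fac2) +
                 matrix(rnorm(20 * s, sd = 0.3), 20, s))
    X[3, ] <- X[3, ] + cls * 1.2
    X[27, ] <- X[27, ] - cls * 1.2
    dimnames(X) <- list(sprintf("g%03d", 1:40), sprintf("s%03d", 1:s))
  })
  y <- setNames(factor(ifelse(cls == 0, "A", "B")), colnames(X))
  cfg <- clearfpp_config(clustering_method = "kmeans", k = 2,
                         embedder = embedder_config(method = "pca",
                                                    standardize = FALSE),
                         cluster_scale = "none", seed = 7)
  tb <- clearfpp_scores(X, y, cfg)
  expect_setequal(head(tb$feature_id, 2), c("g003", "g027"))
})

test_that("per-cluster normalization options keep completeness and ordering within clusters", {
  d <- generate_expression(synthetic_spec(n_features = 60, n_samples = 30,
                                          seed = 3))
  for (norm in c("zscore_per_cluster", "rank_per_cluster")) {
    cfg <- clearfpp_config(clustering_method = "kmeans", k = 3,
                           embedder = embedder_config(method = "pca"),
                           score_normalization = norm, seed = 5)
    tb <- clearfpp_scores(d$X, d$y, cfg)
    expect_setequal(tb$feature_id, rownames(d$X))
    raw <- clearfpp_scores(d$X, d$y,
                           clearfpp_config(clustering_method = "kmeans",
                                           k = 3,
                                           embedder = embedder_config(method = "pca"),
                                           seed = 5))
    # normalization is monotone within a cluster: per-cluster order kept
    A <- attr(tb, "assignment")
    for (cid in unique(A$cluster)) {
      ids <- names(A$cluster)[A$cluster == cid]
      o1 <- match(ids, tb$feature_id)
      o2 <- match(ids, raw$feature_id)
      expect_identical(order(o1), order(o2))
    }
  }
})

test_that("select_top returns ranked prefixes with deterministic ties", {
  tb <- score_table(c("a", "b", "c"), c(3, 1, 2))
  expect_identical(select_top(tb, 2), c("a", "c"))
  expect_identical(select_top(tb, 3), c("a", "c", "b"))
  tb2 <- score_table(c("b", "a"), c(5, 5))
  expect_identical(select_top(tb2, 1), "a")
  expect_error(select_top(tb, 4), "between 1 and")
})

test_that("fold-rank aggregation follows the points rule and its bounds", {
  t1 <- score_table(c("x", "y", "z", "w"), c(4, 3, 2, 1))
  agg1 <- aggregate_fold_ranks(list(t1), top_m = 3)
  expect_identical(setNames(agg1$rank_score, agg1$feature_id),
                   c(x = 3, y = 2, z = 1, w = 0))

  t2 <- score_table(c("x", "y", "z", "w"), c(9, 1, 3, 2))
  agg2 <- aggregate_fold_ranks(list(t1, t2), top_m = 100)
  expect_identical(agg2$rank_score[agg2$feature_id == "x"], 100)

  # identical folds: the mean is any single fold's points vector
  agg10 <- aggregate_fold_ranks(rep(list(t1), 10), top_m = 3)
  expect_equal(agg10, agg1, ignore_attr = TRUE)
  expect_true(all(agg10$rank_score >= 0 & agg10$rank_score <= 3))

  t3 <- score_table(c("x", "y", "z", "q"), 1:4)
  expect_error(aggregate_fold_ranks(list(t1, t3)), "universe")
})
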