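pca_cfg <- function(d = 1, std = FALSE)
  embedder_config(method = "pca", n_components = d, standardize = std)

test_that("class partition preserves order, conserves samples, rejects tiny classes", {
  X <- rand_expr(3, 10)
  p <- partition_by_class(X, rep(c("A", "B"), each = 5))
  expect_identical(lapply(p$indices, as.integer),
                   list(A = 1:5, B = 6:10))

  p2 <- partition_by_class(rand_expr(3, 6), c("A", "B", "A", "B", "A", "B"))
  expect_identical(lapply(p2$indices, as.integer),
                   list(A = c(1L, 3L, 5L), B = c(2L, 4L, 6L)))

  y3 <- rep(c("a", "b", "c"), times = c(4, 3, 5))
  p3 <- partition_by_class(rand_expr(2, 12), y3)
  expect_identical(sum(lengths(p3$indices)), 12L)

  expect_error(partition_by_class(X, c(rep("A", 9), "B")), "B")
})

test_that("full-rank embeddings give identically zero scores", {
  X <- rand_expr(5, 30, seed = 12)
  y <- half_labels(X)
  # d >= min(n, s_block - 1) everywhere: every reconstruction is exact
  tb <- clearf_scores(X, y, pca_cfg(5))
  expect_identical(unique(tb$score), 0)
})

test_that("a class-separated feature scores highest, matching the eigen oracle", {
  # one feature constant within each class, others i.i.d. noise; the class
  # amplitude stays below the leading noise eigenvalue so the global
  # one-component embedding cannot absorb the class direction
  withr::with_seed(101, {
    X <- matrix(rnorm(6 * 40), 6, 40)
    X[3, ] <- rep(c(-0.7, 0.7), each = 20)
    dimnames(X) <- list(paste0("g", 1:6), paste0("s", 1:40))
  })
  y <- setNames(factor(rep(c("A", "B"), each = 20)), colnames(X))
  tb <- clearf_scores(X, y, pca_cfg(1), keep_components = TRUE)
  expect_identical(tb$feature_id[1], "g3")
  expect_gt(tb$score[1], 0)

  # exact value via the independent eigen oracle on each block
  r_x <- pca_eigen_oracle(X, 1)$errors
  r_a <- pca_eigen_oracle(X[, 1:20], 1)$errors
  r_b <- pca_eigen_oracle(X[, 21:40], 1)$errors
  oracle_f <- r_x - (r_a + r_b)
  got <- setNames(tb$score, tb$feature_id)[names(oracle_f)]
  expect_equal(got, oracle_f, tolerance = 1e-8)
})

test_that("scores satisfy the additivity identity when components are retained", {
  d <- generate_expression(synthetic_spec(n_features = 60, n_samples = 50,
                                          seed = 4))
  tb <- clearf_scores(d$X, d$y, pca_cfg(2), keep_components = TRUE)
  comp <- attr(tb, "components")
  f <- setNames(tb$score, tb$feature_id)[names(comp$r_x)]
  expect_equal(f + comp$r_sum, comp$r_x, tolerance = 1e-12)
  expect_identical(unname(f), unname(comp$r_x - comp$r_sum))
})

test_that("scoring is invariant under joint sample/label permutation and is deterministic", {
  d <- generate_expression(synthetic_spec(n_features = 40, n_samples = 30,
                                          seed = 8))
  tb1 <- clearf_scores(d$X, d$y, pca_cfg(1))
  tb1b <- clearf_scores(d$X, d$y, pca_cfg(1))
  expect_identical(tb1, tb1b)            # bitwise determinism (pca path)

  perm <- withr::with_seed(3, sample(ncol(d$X)))
  tb2 <- clearf_scores(d$X[, perm], d$y[perm], pca_cfg(1))
  expect_equal(tb2$score, tb1$score, tolerance = 1e-10)
  expect_identical(tb2$feature_id, tb1$feature_id)

  tb3 <- clearf_scores(d$X[, perm], d$y[perm],
                       embedder_config(method = "kpca_rbf"))
  tb3ref <- clearf_scores(d$X, d$y, embedder_config(method = "kpca_rbf"))
  expect_equal(setNames(tb3$score, tb3$feature_id)[tb3ref$feature_id],
               setNames(tb3ref$score, tb3ref$feature_id),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("label permutation degrades planted-feature scores", {
  d <- generate_expression(synthetic_spec(n_features = 150, n_samples = 80,
                                          n_informative = 10, seed = 13))
  tb <- clearf_one_scores(d$X, d$y, pca_cfg())
  planted_mean <- function(t)
    mean(t$score[t$feature_id %in% d$truth$informative])
  base <- planted_mean(tb)
  lower <- vapply(1:20, function(p) {
    yp <- withr::with_seed(500 + p, sample(d$y))
    names(yp) <- names(d$y)
    planted_mean(clearf_one_scores(d$X, yp, pca_cfg())) < base
  }, logical(1))
  # one-sided sign test at alpha = 0.01: >= 16/20 successes
  expect_gte(sum(lower), 16)
})

test_that("clearf_one forwards to clearf with one component, including degenerate n = 1", {
  d <- generate_expression(synthetic_spec(n_features = 30, n_samples = 24,
                                          seed = 5))
  cfg7 <- pca_cfg(7)
  expect_identical(clearf_one_scores(d$X, d$y, cfg7),
                   clearf_scores(d$X, d$y, pca_cfg(1)))

  X1 <- d$X[1, , drop = FALSE]
  tb1 <- clearf_one_scores(X1, d$y, pca_cfg())
  expect_identical(tb1$score, 0)         # 1-D pca with d = 1 is exact

  # constant feature scores zero too
  Xc <- d$X
  Xc["gene_0002", ] <- 7
  tbc <- clearf_one_scores(Xc, d$y, embedder_config(method = "pca"))
  expect_equal(tbc$score[tbc$feature_id == "gene_0002"], 0,
               tolerance = 1e-10)
})

test_that("multi-class scoring sums over all class blocks", {
  d <- generate_expression(synthetic_spec(n_features = 40, n_samples = 60,
                                          n_classes = 3, seed = 6))
  tb <- clearf_scores(d$X, d$y, pca_cfg(1), keep_components = TRUE)
  comp <- attr(tb, "components")
  expect_length(comp$r_class, 3L)
  expect_equal(comp$r_sum, Reduce(`+`, comp$r_class))
  # planted features should still surface with three classes
  expect_gt(mean(d$truth$informative %in% head(tb$feature_id, 40)), 0.5)
})
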