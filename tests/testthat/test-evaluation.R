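test_that("stratified folds are deterministic and balanced within one sample", {
  y <- factor(rep(c("A", "B"), times = c(33, 47)))
  f1 <- stratified_folds(y, 10, seed = 2)
  f2 <- stratified_folds(y, 10, seed = 2)
  expect_identical(f1, f2)
  expect_identical(sort(unique(f1)), 1:10)
  for (fold in 1:10) {
    for (cl in levels(y)) {
      n_cl <- sum(y == cl)
      got <- sum(y[f1 == fold] == cl)
      expect_lte(abs(got - n_cl / 10), 1)
    }
  }
})

test_that("selectors only ever see training samples", {
  d <- generate_expression(synthetic_spec(n_features = 30, n_samples = 40,
                                          seed = 1))
  seen <- list()
  spy <- function(X, y) {
    seen[[length(seen) + 1L]] <<- colnames(X)
    score_table(rownames(X), seq_len(nrow(X)))
  }
  cv <- cv_config(n_select = 5, n_folds = 4, seed = 3)
  res <- cross_validate(d$X, d$y, spy, cv)
  for (f in seq_len(4)) {
    test_ids <- colnames(d$X)[res$fold_id == f]
    expect_length(intersect(seen[[f]], test_ids), 0L)
    expect_setequal(seen[[f]], setdiff(colnames(d$X), test_ids))
  }
})

test_that("a perfectly separating feature yields AUC 1 with the logistic classifier", {
  withr::with_seed(9, {
    X <- matrix(rnorm(5 * 40), 5, 40)
    X[2, ] <- rep(c(0, 10), each = 20) + rnorm(40, sd = 0.1)
    dimnames(X) <- list(paste0("g", 1:5), paste0("s", 1:40))
  })
  y <- setNames(factor(rep(c("neg", "pos"), each = 20)), colnames(X))
  sel <- function(X, y) score_table(rownames(X),
                                    as.numeric(rownames(X) == "g2"))
  res <- cross_validate(X, y, sel, cv_config(n_select = 1, n_folds = 4,
                                             seed = 1))
  expect_identical(res$fold_auc, rep(1, 4))
  expect_identical(res$mean_auc, 1)
})

test_that("the oracle selector saturates AUC and a random selector on noise sits near 0.5", {
  oracle_auc <- random_auc <- numeric(5)
  for (s in 1:5) {
    d <- generate_expression(synthetic_spec(n_features = 200,
                                            n_samples = 100, seed = s))
    cv <- cv_config(n_select = 20, n_folds = 5, seed = s)
    oracle_auc[s] <- cross_validate(d$X, d$y,
                                    selector_oracle(d$truth$informative),
                                    cv)$mean_auc
    dn <- generate_expression(synthetic_spec(n_features = 200,
                                             n_samples = 100,
                                             n_informative = 0,
                                             seed = 50 + s))
    random_auc[s] <- cross_validate(dn$X, dn$y, selector_random(seed = s),
                                    cv)$mean_auc
  }
  expect_gte(mean(oracle_auc), 0.95)
  expect_gte(mean(random_auc), 0.35)
  expect_lte(mean(random_auc), 0.65)
})

test_that("compare_selectors pairs folds across selectors and matches cross_validate", {
  d <- generate_expression(synthetic_spec(n_features = 50, n_samples = 60,
                                          seed = 11))
  cv <- cv_config(n_select = 10, n_folds = 4, seed = 7)
  sel <- selector_oracle(d$truth$informative)
  tidy <- compare_selectors(d$X, d$y, list(one = sel, two = sel),
                            m_grid = 10, cv)
  a1 <- tidy$auc[tidy$selector == "one"]
  a2 <- tidy$auc[tidy$selector == "two"]
  expect_identical(a1, a2)               # identical selectors, paired folds

  ref <- cross_validate(d$X, d$y, sel, cv)
  expect_equal(a1, ref$fold_auc)
  expect_identical(nrow(tidy), 2L * 4L)
  expect_identical(names(attr(tidy, "summary")), c("selector", "m", "auc"))
})

test_that("the four-layer DNN classifier learns a separable problem", {
  withr::with_seed(15, {
    X <- matrix(rnorm(4 * 60), 4, 60)
    X[1, ] <- rep(c(-1.5, 1.5), each = 30) + rnorm(60, sd = 0.5)
    dimnames(X) <- list(paste0("g", 1:4), paste0("s", 1:60))
  })
  y <- setNames(factor(rep(c("A", "B"), each = 30)), colnames(X))
  sel <- function(X, y) score_table(rownames(X), c(4, 1, 1, 1))
  cv <- cv_config(n_select = 2, n_folds = 3, classifier = "paper_dnn",
                  seed = 2, dnn_epochs = 300)
  res <- cross_validate(X, y, sel, cv)
  expect_gte(res$mean_auc, 0.9)
  # seeded: bitwise reproducible
  expect_identical(cross_validate(X, y, sel, cv)$fold_auc, res$fold_auc)
})

test_that("degenerate folds and oversized selections error clearly", {
  d <- generate_expression(synthetic_spec(n_features = 10, n_samples = 20,
                                          n_informative = 3, seed = 1))
  expect_error(cross_validate(d$X, d$y, selector_random(1),
                              cv_config(n_select = 11, n_folds = 4)),
               "exceeds")
  y_imbal <- setNames(factor(c(rep("A", 17), rep("B", 3))), colnames(d$X))
  expect_error(
    cross_validate(d$X, y_imbal, selector_random(1),
                   cv_config(n_select = 2, n_folds = 4, stratified = FALSE,
                             seed = 4)),
    "class")
})
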