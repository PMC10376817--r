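# Cross-validated evaluation of feature selectors: stratified k-fold CV
# where the selector is fitted on training folds only, followed by a
# classifier on the selected features and AUC on the held-out fold.

#' Cross-validation configuration
#'
#' @param n_select number of top-ranked features handed to the classifier.
#' @param n_folds number of folds, default 10.
#' @param classifier `"logistic"` (default; fast baseline via
#'   [stats::glm()]) or `"paper_dnn"`: a four-layer feed-forward network
#'   with hidden widths `2m` and `m` (m = `n_select`), tanh activations,
#'   sigmoid output, trained full-batch with Adam at learning rate 1e-3
#'   for 500 epochs.
#' @param seed RNG seed controlling fold assignment and classifier
#'   initialization.
#' @param stratified keep per-fold class proportions within one sample of
#'   the global proportions, default `TRUE`.
#' @param dnn_epochs,dnn_learning_rate training schedule of the DNN
#'   classifier.
#' @return list of class `cv_config`.
#' @export
cv_config <- function(n_select,
                      n_folds = 10L,
                      classifier = c("logistic", "paper_dnn"),
                      seed = 1L,
                      stratified = TRUE,
                      dnn_epochs = 500L,
                      dnn_learning_rate = 1e-3) {
  classifier <- match.arg(classifier)
  stopifnot(n_folds >= 2L, n_select >= 1L)
  structure(list(n_select = as.integer(n_select),
                 n_folds = as.integer(n_folds),
                 classifier = classifier,
                 seed = as.integer(seed),
                 stratified = isTRUE(stratified),
                 dnn_epochs = as.integer(dnn_epochs),
                 dnn_learning_rate = dnn_learning_rate),
            class = "cv_config")
}

#' Deterministic (stratified) fold assignment
#'
#' @param y class labels.
#' @param n_folds number of folds.
#' @param seed RNG seed.
#' @param stratified if `TRUE` (default), deal each class's shuffled
#'   samples round-robin across folds so per-fold class proportions stay
#'   within one sample of the global proportions.
#' @return integer vector of fold ids in `1..n_folds`, one per sample.
#' @export
stratified_folds <- function(y, n_folds, seed = 1L, stratified = TRUE) {
  y <- if (is.factor(y)) y else factor(y)
  n_folds <- as.integer(n_folds)
  s <- length(y)
  fold <- integer(s)
  withr::with_seed(seed, {
    if (stratified) {
      offset <- 0L
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        # rotate the dealing start so small classes don't pile on fold 1
        fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
        offset <- offset + length(idx)
      }
    } else {
      fold <- ((sample(s) - 1L) %% n_folds) + 1L
    }
  })
  fold
}

# ---- selector constructors -------------------------------------------------
# A selector is a function(X_train, y_train) -> feature_score_table.

#' Selector constructors for the CV harness
#'
#' Each constructor returns a `function(X, y)` producing a
#' `feature_score_table`, the plug-in interface [cross_validate()]
#' expects. `selector_oracle` scores a known informative set above all
#' other features (for harness calibration on synthetic data);
#' `selector_random` draws i.i.d. scores, advancing a derived seed on
#' every call so folds differ.
#'
#' @param cfg an [embedder_config()] or [clearfpp_config()].
#' @param informative_ids character vector of ground-truth informative
#'   feature ids.
#' @param seed integer seed for the random selector.
#' @return a selector function.
#' @name selectors
NULL

#' @rdname selectors
#' @export
selector_clearf <- function(cfg = embedder_config(n_components = 2L)) {
  function(X, y) clearf_scores(X, y, cfg)
}

#' @rdname selectors
#' @export
selector_clearf_one <- function(cfg = embedder_config()) {
  function(X, y) clearf_one_scores(X, y, cfg)
}

#' @rdname selectors
#' @export
selector_clearfpp <- function(cfg = clearfpp_config()) {
  function(X, y) clearfpp_scores(X, y, cfg)
}

#' @rdname selectors
#' @export
selector_oracle <- function(informative_ids) {
  force(informative_ids)
  function(X, y) {
    score_table(rownames(X),
                as.numeric(rownames(X) %in% informative_ids))
  }
}

#' @rdname selectors
#' @export
selector_random <- function(seed = 1L) {
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  function(X, y) {
    counter$i <- counter$i + 1L
    sc <- withr::with_seed(derive_seed(seed, counter$i),
                           stats::runif(nrow(X)))
    score_table(rownames(X), sc)
  }
}

# ---- classifiers -----------------------------------------------------------

# z-score by training statistics; returns scaled train/test (samples x feats)
scale_by_train <- function(Xtr, Xte) {
  mu <- rowMeans(Xtr)
  sdev <- apply(Xtr, 1L, stats::sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  list(tr = t((Xtr - mu) / sdev), te = t((Xte - mu) / sdev))
}

fit_predict_logistic <- function(Xtr, ytr, Xte) {
  sc <- scale_by_train(Xtr, Xte)
  df_tr <- as.data.frame(sc$tr)
  names(df_tr) <- paste0("f", seq_len(ncol(df_tr)))
  df_tr$.y <- as.integer(ytr == levels(ytr)[2L])
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df_tr,
                                     family = stats::binomial()))
  df_te <- as.data.frame(sc$te)
  names(df_te) <- paste0("f", seq_len(ncol(df_te)))
  suppressWarnings(as.numeric(stats::predict(fit, df_te,
                                             type = "response")))
}

fit_predict_dnn <- function(Xtr, ytr, Xte, m, epochs, lr, seed) {
  sc <- scale_by_train(Xtr, Xte)
  y01 <- as.numeric(ytr == levels(ytr)[2L])
  n <- nrow(sc$tr)
  withr::with_seed(seed, {
    net <- mlp_init(c(ncol(sc$tr), 2L * m, m, 1L),
                    acts = c("tanh", "tanh", "linear"))
    opt <- mlp_opt_init(net)
    for (t in seq_len(epochs)) {
      A <- mlp_forward(net, sc$tr)
      p <- 1 / (1 + exp(-A[[length(A)]][, 1L]))
      dOut <- matrix((p - y01) / n, ncol = 1L)  # BCE through sigmoid
      bk <- mlp_backward(net, A, dOut)
      st <- mlp_adam_step(net, bk$grads, opt, lr, t)
      net <- st$net; opt <- st$opt
    }
    A <- mlp_forward(net, sc$te)
    1 / (1 + exp(-A[[length(A)]][, 1L]))
  })
}

fold_auc <- function(y_te, p) {
  as.numeric(pROC::auc(pROC::roc(response = y_te, predictor = p,
                                 levels = levels(y_te), direction = "<",
                                 quiet = TRUE)))
}

# ---- the harness -----------------------------------------------------------

#' Cross-validated feature-selection evaluation
#'
#' For each fold: fit the selector on the training samples only, take the
#' top `cv$n_select` features, train the classifier on the training
#' samples restricted to those features, and measure AUC on the held-out
#' fold (two-class labels; the second factor level is treated as
#' positive). Selectors never see test samples, so there is no selection
#' leakage.
#'
#' @param X expression matrix (features x samples).
#' @param y two-class labels, one per sample.
#' @param selector `function(X_train, y_train) -> feature_score_table`;
#'   see [selectors].
#' @param cv a [cv_config()].
#' @return list of class `cv_result`: `fold_auc` (numeric, one per fold),
#'   `mean_auc`, `selected` (list of per-fold feature-id vectors),
#'   `fold_id` (per-sample fold assignment), `config`.
#' @export
cross_validate <- function(X, y, selector, cv) {
  validate_expression_matrix(X)
  y <- as_label_vector(y, X)
  stopifnot(inherits(cv, "cv_config"), is.function(selector))
  if (nlevels(y) != 2L)
    stop("the CV harness evaluates two-class problems", call. = FALSE)
  if (cv$n_select > nrow(X))
    stop("n_select exceeds the number of features", call. = FALSE)

  fold <- stratified_folds(y, cv$n_folds, seed = cv$seed,
                           stratified = cv$stratified)
  aucs <- numeric(cv$n_folds)
  selected <- vector("list", cv$n_folds)
  for (f in seq_len(cv$n_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (nlevels(droplevels(y[te])) < 2L || nlevels(droplevels(y[tr])) < 2L)
      stop("fold ", f, " does not contain every class; ",
           "use stratified folds or fewer folds", call. = FALSE)
    tbl <- selector(X[, tr, drop = FALSE], y[tr])
    feats <- select_top(tbl, cv$n_select)
    selected[[f]] <- feats
    Xtr <- X[feats, tr, drop = FALSE]
    Xte <- X[feats, te, drop = FALSE]
    p <- if (cv$classifier == "logistic") {
      fit_predict_logistic(Xtr, y[tr], Xte)
    } else {
      fit_predict_dnn(Xtr, y[tr], Xte, m = cv$n_select,
                      epochs = cv$dnn_epochs, lr = cv$dnn_learning_rate,
                      seed = derive_seed(cv$seed, f))
    }
    aucs[f] <- fold_auc(droplevels(y[te]), p)
  }
  structure(list(fold_auc = aucs, mean_auc = mean(aucs),
                 selected = selected, fold_id = fold, config = cv),
            class = "cv_result")
}

#' Compare several selectors under paired folds
#'
#' Runs every selector over the same fold splits and every feature count
#' in `m_grid`, refitting each selector once per fold and reusing its
#' ranking across `m` values (a paired design: AUC differences between
#' selectors are not confounded by fold composition).
#'
#' @param X expression matrix.
#' @param y two-class labels.
#' @param selectors named list of selector functions.
#' @param m_grid integer vector of feature counts to evaluate.
#' @param cv a [cv_config()]; its `n_select` is overridden by `m_grid`.
#' @return data frame with columns `selector`, `m`, `fold`, `auc`, one
#'   row per (selector, m, fold); attribute `summary` holds the mean AUC
#'   per (selector, m).
#' @export
compare_selectors <- function(X, y, selectors, m_grid, cv) {
  validate_expression_matrix(X)
  y <- as_label_vector(y, X)
  stopifnot(length(selectors) >= 1L, !is.null(names(selectors)),
            all(nzchar(names(selectors))), all(m_grid >= 1L),
            max(m_grid) <= nrow(X))
  fold <- stratified_folds(y, cv$n_folds, seed = cv$seed,
                           stratified = cv$stratified)
  rows <- list()
  for (sel_name in names(selectors)) {
    selector <- selectors[[sel_name]]
    for (f in seq_len(cv$n_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      tbl <- selector(X[, tr, drop = FALSE], y[tr])
      for (m in m_grid) {
        feats <- select_top(tbl, m)
        Xtr <- X[feats, tr, drop = FALSE]
        Xte <- X[feats, te, drop = FALSE]
        p <- if (cv$classifier == "logistic") {
          fit_predict_logistic(Xtr, y[tr], Xte)
        } else {
          fit_predict_dnn(Xtr, y[tr], Xte, m = m,
                          epochs = cv$dnn_epochs,
                          lr = cv$dnn_learning_rate,
                          seed = derive_seed(cv$seed, f))
        }
        rows[[length(rows) + 1L]] <-
          data.frame(selector = sel_name, m = m, fold = f,
                     auc = fold_auc(droplevels(y[te]), p),
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summary") <- stats::aggregate(auc ~ selector + m, out, mean)
  out
}
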