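# Feature-wise clustering: each feature's expression profile across
# samples is one point; clusters are groups of co-varying features that
# the clustered scoring variant embeds separately.

#' DEC configuration
#'
#' Hyperparameters of the Deep Embedded Clustering routine used by
#' [dec_features()]. The architecture is deliberately small: the clustered
#' objects are feature profiles (hundreds to a few thousand points of
#' dimension = number of samples), not image corpora.
#'
#' @param encoder_dims widths of the encoder layers, ending in the latent
#'   dimension; default `c(64, 32, 10)` (input width is taken from the
#'   data). Latent dimension must be >= 2.
#' @param pretrain_epochs full-batch epochs of autoencoder pretraining
#'   (squared reconstruction loss), default 100.
#' @param finetune_update_interval batches between target-distribution
#'   updates during self-training; training is full-batch, so this counts
#'   epochs. Default 30.
#' @param convergence_tol stop self-training when the fraction of features
#'   changing cluster between consecutive target updates falls below this;
#'   default 0.001.
#' @param max_finetune_epochs hard cap on self-training epochs, default 300.
#' @param student_t_df degrees of freedom of the Student-t kernel in the
#'   soft assignment, default 1.
#' @param learning_rate Adam learning rate for both phases, default 1e-3.
#' @param seed RNG seed; when `NULL` the caller's seed argument is used.
#' @return list of class `dec_config`.
#' @export
dec_config <- function(encoder_dims = c(64L, 32L, 10L),
                       pretrain_epochs = 100L,
                       finetune_update_interval = 30L,
                       convergence_tol = 0.001,
                       max_finetune_epochs = 300L,
                       student_t_df = 1,
                       learning_rate = 1e-3,
                       seed = NULL) {
  stopifnot(length(encoder_dims) >= 1L, rev(encoder_dims)[1L] >= 2L,
            convergence_tol > 0, convergence_tol < 1,
            student_t_df > 0, pretrain_epochs >= 1L,
            finetune_update_interval >= 1L)
  structure(list(encoder_dims = as.integer(encoder_dims),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_update_interval = as.integer(finetune_update_interval),
                 convergence_tol = convergence_tol,
                 max_finetune_epochs = as.integer(max_finetune_epochs),
                 student_t_df = student_t_df,
                 learning_rate = learning_rate,
                 seed = seed),
            class = "dec_config")
}

cluster_assignment <- function(cluster, k, method, seed, extra = NULL) {
  out <- structure(list(cluster = cluster,
                        k = as.integer(k),
                        effective_k = length(unique(cluster)),
                        method = method,
                        seed = seed),
                   class = "cluster_assignment")
  out[names(extra)] <- extra
  out
}

# Points matrix for clustering: features as rows, optional per-profile
# z-scoring so clusters reflect profile shape rather than magnitude.
cluster_points <- function(X, scale) {
  P <- X
  if (scale == "profile") {
    mu <- rowMeans(P)
    sdev <- apply(P, 1L, stats::sd)
    sdev[sdev == 0 | !is.finite(sdev)] <- 1
    P <- (P - mu) / sdev
  }
  P
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers by
# sampling points with probability proportional to squared distance from
# the nearest chosen center.
kmeanspp_centers <- function(P, k) {
  n <- nrow(P)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums((P - matrix(P[centers[1L], ], n, ncol(P), byrow = TRUE))^2)
    for (j in 2L:k) {
      if (all(d2 == 0)) {
        pool <- setdiff(seq_len(n), centers[seq_len(j - 1L)])
        centers[j] <- pool[sample.int(length(pool), 1L)]
      } else {
        centers[j] <- sample.int(n, 1L, prob = d2)
      }
      dn <- rowSums((P - matrix(P[centers[j], ], n, ncol(P), byrow = TRUE))^2)
      d2 <- pmin(d2, dn)
    }
  }
  P[centers, , drop = FALSE]
}

# Lloyd's algorithm seeded by k-means++, best of n_init restarts by
# within-cluster sum of squares. Uses the caller's RNG state.
kmeans_points <- function(P, k, n_init = 10L, iter_max = 100L) {
  if (k == 1L)
    return(list(cluster = rep(1L, nrow(P)),
                centers = matrix(colMeans(P), 1L),
                tot.withinss = sum(sweep(P, 2L, colMeans(P))^2)))
  if (k == nrow(P))
    return(list(cluster = seq_len(nrow(P)), centers = P, tot.withinss = 0))
  best <- NULL
  for (r in seq_len(n_init)) {
    init <- kmeanspp_centers(P, k)
    km <- suppressWarnings(
      stats::kmeans(P, centers = init, iter.max = iter_max,
                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

#' Cluster features with k-means
#'
#' Treats each feature's expression profile across samples as a point and
#' partitions the features into `k` clusters with Lloyd's algorithm,
#' k-means++ initialization, and the best of `n_init` restarts by inertia.
#' Deterministic given `seed`.
#'
#' @param X expression matrix (features x samples).
#' @param k number of clusters, `1 <= k <= nrow(X)`.
#' @param seed integer RNG seed.
#' @param scale `"profile"` (default) z-scores each feature profile so
#'   clusters reflect shape, not magnitude; `"none"` clusters raw
#'   profiles.
#' @param n_init number of k-means++ restarts, default 10.
#' @return a `cluster_assignment`: list with `cluster` (named integer
#'   vector, values in `1..k`), `k`, `effective_k`, `method`, `seed`.
#' @export
kmeans_features <- function(X, k, seed = 1L, scale = c("profile", "none"),
                            n_init = 10L) {
  validate_expression_matrix(X)
  scale <- match.arg(scale)
  k <- as.integer(k)
  if (k < 1L || k > nrow(X))
    stop("k must be between 1 and the number of features (", nrow(X), ")",
         call. = FALSE)
  P <- cluster_points(X, scale)
  km <- withr::with_seed(seed, kmeans_points(P, k, n_init = n_init))
  cl <- stats::setNames(as.integer(km$cluster), rownames(X))
  cluster_assignment(cl, k, "kmeans", seed)
}

# Student-t soft assignment of latent points Z to centroids Mu.
dec_soft_assign <- function(Z, Mu, df) {
  d2 <- outer(rowSums(Z^2), rep(1, nrow(Mu))) +
    outer(rep(1, nrow(Z)), rowSums(Mu^2)) - 2 * Z %*% t(Mu)
  d2[d2 < 0] <- 0
  B <- 1 / (1 + d2 / df)
  Qu <- B^((df + 1) / 2)
  list(Q = Qu / rowSums(Qu), B = B)
}

# Sharpened target distribution: p_ij = (q_ij^2 / f_j) / normalizer.
dec_target <- function(Q) {
  f <- colSums(Q)
  Pu <- sweep(Q^2, 2L, f, "/")
  Pu / rowSums(Pu)
}

dec_kl <- function(P, Q) {
  sum(P * (log(pmax(P, 1e-12)) - log(pmax(Q, 1e-12)))) / nrow(P)
}

#' Cluster features with Deep Embedded Clustering
#'
#' DEC in three phases: (1) pretrain a small symmetric autoencoder on the
#' feature profiles with squared reconstruction loss; (2) initialize `k`
#' centroids by k-means (k-means++ seeding) in the latent space; (3)
#' self-train by minimizing the KL divergence between the Student-t soft
#' assignment `Q` of latent points to centroids and the sharpened target
#' distribution `P` derived from `Q`, updating both the encoder weights
#' and the centroids by full-batch Adam. The target is refreshed every
#' `finetune_update_interval` epochs; training stops when the fraction of
#' features changing cluster between refreshes drops below
#' `convergence_tol` (or at `max_finetune_epochs`). Deterministic given
#' `seed`.
#'
#' Profiles are centred and scaled by a single global mean/sd before
#' training (a scalar affine map, so cluster geometry is unchanged) to
#' keep tanh units in range on raw expression magnitudes.
#'
#' @inheritParams kmeans_features
#' @param cfg a [dec_config()].
#' @return a `cluster_assignment` (method `"dec"`) with extra elements
#'   `kl_trace` (data frame: per target refresh, KL at refresh and at the
#'   end of the interval) and `changed_fraction`.
#' @export
dec_features <- function(X, k, cfg = dec_config(), seed = 1L,
                         scale = c("profile", "none")) {
  validate_expression_matrix(X)
  scale <- match.arg(scale)
  k <- as.integer(k)
  n <- nrow(X)
  if (k < 1L || k > n)
    stop("k must be between 1 and the number of features (", n, ")",
         call. = FALSE)
  if (n < 10L * k)
    warning("only ", n, " features for k = ", k,
            " clusters; DEC is intended for n >= 10k points", call. = FALSE)
  if (!is.null(cfg$seed)) seed <- cfg$seed
  if (k == 1L) {
    return(cluster_assignment(stats::setNames(rep(1L, n), rownames(X)),
                              1L, "dec", seed))
  }

  P0 <- cluster_points(X, scale)
  gmu <- mean(P0)
  gsd <- stats::sd(as.vector(P0))
  if (!is.finite(gsd) || gsd == 0) gsd <- 1
  Pts <- (P0 - gmu) / gsd

  df <- cfg$student_t_df
  res <- withr::with_seed(seed, {
    enc_dims <- cfg$encoder_dims
    # latent width cannot exceed what the data supports
    ae <- train_autoencoder(Pts, enc_dims, cfg$pretrain_epochs,
                            lr = cfg$learning_rate)
    enc <- encoder_of(ae)
    Z <- mlp_forward(enc, Pts)[[length(enc$layers) + 1L]]
    km <- kmeans_points(Z, k, n_init = 10L)
    Mu <- km$centers
    opt <- mlp_opt_init(enc)
    optMu <- list(m = Mu * 0, v = Mu * 0)

    sa <- dec_soft_assign(Z, Mu, df)
    Ptar <- dec_target(sa$Q)
    assign_prev <- max.col(sa$Q, ties.method = "first")
    kl_trace <- list()
    kl_start <- dec_kl(Ptar, sa$Q)
    changed <- NA_real_
    t_step <- 0L

    for (epoch in seq_len(cfg$max_finetune_epochs)) {
      if (epoch > 1L &&
          (epoch - 1L) %% cfg$finetune_update_interval == 0L) {
        sa_now <- dec_soft_assign(Z, Mu, df)
        kl_trace[[length(kl_trace) + 1L]] <-
          c(kl_start = kl_start, kl_end = dec_kl(Ptar, sa_now$Q))
        assign_now <- max.col(sa_now$Q, ties.method = "first")
        changed <- mean(assign_now != assign_prev)
        assign_prev <- assign_now
        if (changed < cfg$convergence_tol) break
        Ptar <- dec_target(sa_now$Q)
        kl_start <- dec_kl(Ptar, sa_now$Q)
      }
      # gradient of mean KL(P || Q) w.r.t. latent points and centroids
      A <- mlp_forward(enc, Pts)
      Z <- A[[length(A)]]
      sa <- dec_soft_assign(Z, Mu, df)
      G <- ((df + 1) / df) * sa$B * (Ptar - sa$Q) / n
      dZ <- rowSums(G) * Z - G %*% Mu
      dMu <- -(t(G) %*% Z - colSums(G) * Mu)
      t_step <- t_step + 1L
      bk <- mlp_backward(enc, A, dZ)
      st <- mlp_adam_step(enc, bk$grads, opt, cfg$learning_rate, t_step)
      enc <- st$net; opt <- st$opt
      um <- adam_update(Mu, dMu, optMu, cfg$learning_rate, t_step)
      Mu <- um$theta; optMu <- um$state
      Z <- mlp_forward(enc, Pts)[[length(enc$layers) + 1L]]
    }
    sa <- dec_soft_assign(Z, Mu, df)
    list(assign = max.col(sa$Q, ties.method = "first"),
         kl_trace = kl_trace, changed = changed)
  })

  cl <- stats::setNames(as.integer(res$assign), rownames(X))
  if (length(unique(cl)) < k)
    warning("DEC converged with ", length(unique(cl)),
            " non-empty clusters out of k = ", k, call. = FALSE)
  kl_df <- if (length(res$kl_trace))
    as.data.frame(do.call(rbind, res$kl_trace)) else
    data.frame(kl_start = numeric(), kl_end = numeric())
  cluster_assignment(cl, k, "dec", seed,
                     extra = list(kl_trace = kl_df,
                                  changed_fraction = res$changed))
}

#' Split a matrix by cluster assignment
#'
#' @param X expression matrix the assignment was computed on.
#' @param A a `cluster_assignment` from [kmeans_features()] or
#'   [dec_features()].
#' @return list of one matrix per non-empty cluster (all samples
#'   retained, features in original relative order), named by cluster
#'   index.
#' @export
split_by_cluster <- function(X, A) {
  stopifnot(inherits(A, "cluster_assignment"))
  if (!identical(names(A$cluster), rownames(X)))
    stop("cluster assignment was not computed on this matrix's features",
         call. = FALSE)
  ids <- sort(unique(A$cluster))
  stats::setNames(
    lapply(ids, function(cid) X[A$cluster == cid, , drop = FALSE]),
    as.character(ids))
}
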