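# Shared fixtures and independent oracles, built in code.

# Random dense expression matrix with ids.
rand_expr <- function(n, s, seed = 1L) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * s), n, s)
    dimnames(X) <- list(sprintf("g%03d", seq_len(n)),
                        sprintf("s%03d", seq_len(s)))
    X
  })
}

# Balanced two-class labels aligned to a matrix.
half_labels <- function(X) {
  s <- ncol(X)
  setNames(factor(rep(c("A", "B"), length.out = s)), colnames(X))
}

# Independent PCA reconstruction oracle: eigendecomposition of the sample
# covariance (denominator s - 1), truncated projection about the mean.
# Deliberately separate from the prcomp/svd path used by the package.
pca_eigen_oracle <- function(X, d) {
  Xt <- t(X)
  mu <- colMeans(Xt)
  C <- cov(Xt)
  ev <- eigen(C, symmetric = TRUE)
  U <- ev$vectors[, seq_len(d), drop = FALSE]
  Rec <- sweep(Xt, 2, mu) %*% U %*% t(U)
  Res <- sweep(Xt, 2, mu) - Rec
  list(errors = setNames(colSums(Res^2), rownames(X)),
       eigenvalues = ev$values)
}

# Full reconstruction from the same eigen route, on the original scale.
pca_oracle_reconstruction <- function(X, d) {
  Xt <- t(X)
  mu <- colMeans(Xt)
  ev <- eigen(cov(Xt), symmetric = TRUE)
  U <- ev$vectors[, seq_len(d), drop = FALSE]
  out <- t(sweep(sweep(Xt, 2, mu) %*% U %*% t(U), 2, mu, "+"))
  dimnames(out) <- dimnames(X)
  out
}

# Two well-separated feature blocks: constant means +-10, noise sd 0.1.
two_block_features <- function(seed, n_per_block = 60L, s = 20L) {
  withr::with_seed(seed, {
    X <- rbind(matrix(10 + rnorm(n_per_block * s, sd = 0.1), n_per_block, s),
               matrix(-10 + rnorm(n_per_block * s, sd = 0.1), n_per_block, s))
    dimnames(X) <- list(sprintf("g%03d", seq_len(2L * n_per_block)),
                        sprintf("s%02d", seq_len(s)))
    X
  })
}

# TRUE iff an assignment matches block membership up to label swap.
partitions_agree <- function(cluster, truth) {
  length(unique(paste(cluster, truth))) == length(unique(truth))
}
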