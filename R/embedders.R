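# Low-dimensional embedding + reconstruction backends.
#
# Samples (columns of the expression matrix) are the embedded points;
# features are coordinates. PCA reconstructs with the rank-d truncated
# projection about the sample mean; kernel PCA (RBF) reconstructs through
# a ridge-regression pre-image map from kernel coordinates back to input
# space, trained on the fitted block itself.

#' Embedder configuration
#'
#' @param method `"kpca_rbf"` (kernel PCA with an RBF kernel, the default
#'   used for scoring) or `"pca"` (linear PCA).
#' @param n_components number of embedding components `d` (>= 1). Clipped
#'   with a warning when a fitted block is too small to support it.
#' @param rbf_gamma RBF kernel width; `"auto"` (default) uses
#'   `1 / (n_features * var(values))` of the fitted block, or
#'   `"median"` for the median-heuristic `1 / median(pairwise sq. dist.)`.
#'   A positive number fixes it explicitly.
#' @param preimage_ridge_alpha ridge penalty of the pre-image regression
#'   (kernel PCA only), default 1.
#' @param standardize z-score features with the statistics of the fitted
#'   block before embedding; the reconstruction is always returned on the
#'   original scale. Default `TRUE` (RBF kernels are scale-sensitive and
#'   per-block standardization keeps class blocks comparable).
#' @param error_aggregation `"sum"` (default) or `"mean"`: whether the
#'   per-feature reconstruction error sums or averages squared residuals
#'   over samples. The scoring identity uses sums so that whole-data and
#'   class-block errors stay in the same units of total squared error.
#' @return a list of class `embedder_config`.
#' @export
embedder_config <- function(method = c("kpca_rbf", "pca"),
                            n_components = 1L,
                            rbf_gamma = "auto",
                            preimage_ridge_alpha = 1.0,
                            standardize = TRUE,
                            error_aggregation = c("sum", "mean")) {
  method <- match.arg(method)
  error_aggregation <- match.arg(error_aggregation)
  stopifnot(length(n_components) == 1L, n_components >= 1)
  if (is.numeric(rbf_gamma)) stopifnot(rbf_gamma > 0)
  else rbf_gamma <- match.arg(rbf_gamma, c("auto", "median"))
  stopifnot(is.numeric(preimage_ridge_alpha), preimage_ridge_alpha > 0)
  structure(list(method = method,
                 n_components = as.integer(n_components),
                 rbf_gamma = rbf_gamma,
                 preimage_ridge_alpha = preimage_ridge_alpha,
                 standardize = isTRUE(standardize),
                 error_aggregation = error_aggregation),
            class = "embedder_config")
}

# Clip the requested d to what the block supports, warning when it bites.
clip_components <- function(d, n, s) {
  d_max <- max(1L, min(n, s - 1L))
  if (d > d_max) {
    warning("n_components clipped from ", d, " to ", d_max,
            " for a block of ", n, " features x ", s, " samples",
            call. = FALSE)
    d <- d_max
  }
  as.integer(d)
}

#' Embed a block and reconstruct it
#'
#' Fits the configured embedding to the samples of `X_block`, maps them to
#' `d` dimensions and back, and returns the reconstruction with the same
#' shape and dimnames as the input (on the original scale even when the
#' fit standardizes internally).
#'
#' For `method = "pca"` the reconstruction is the truncated projection
#' \eqn{\bar{X} + U_d U_d^T (X - \bar{X})} over samples. When the clipped
#' `d` already spans the block (`d >= min(n, s - 1)`), the projection is
#' the identity and `X_block` is returned unchanged. For
#' `method = "kpca_rbf"`, sample coordinates in kernel PCA space are
#' mapped back to feature space by ridge regression fitted on the block
#' itself; a zero-variance block falls back to PCA with a warning.
#'
#' @param X_block expression matrix (features x samples, >= 2 samples).
#' @param cfg an [embedder_config()].
#' @return numeric matrix, same dimensions and dimnames as `X_block`.
#' @export
fit_reconstruct <- function(X_block, cfg = embedder_config()) {
  validate_expression_matrix(X_block)
  stopifnot(inherits(cfg, "embedder_config"))
  n <- nrow(X_block)
  s <- ncol(X_block)
  d <- clip_components(cfg$n_components, n, s)

  # full-rank linear projection is the identity: return the block as-is
  # (exact, independent of standardization)
  if (cfg$method == "pca" && d >= min(n, s - 1L))
    return(X_block)

  Xt <- t(X_block)                      # s x n: samples are points
  if (cfg$standardize) {
    mu <- colMeans(Xt)
    sdev <- apply(Xt, 2L, stats::sd)
    sdev[sdev == 0 | !is.finite(sdev)] <- 1
    Z <- sweep(sweep(Xt, 2L, mu, "-"), 2L, sdev, "/")
  } else {
    Z <- Xt
  }

  method <- cfg$method
  if (method == "kpca_rbf") {
    gamma <- rbf_gamma_value(Z, cfg$rbf_gamma)
    if (!is.finite(gamma) || gamma <= 0) {
      warning("zero-variance block under kpca_rbf with auto gamma; ",
              "falling back to pca", call. = FALSE)
      method <- "pca"
    }
  }

  Rec <- if (method == "pca") {
    reconstruct_pca(Z, d)
  } else {
    tryCatch(reconstruct_kpca(Z, d, gamma, cfg$preimage_ridge_alpha),
             error = function(e) {
               warning("kernel PCA failed (", conditionMessage(e),
                       "); falling back to pca", call. = FALSE)
               reconstruct_pca(Z, d)
             })
  }

  if (cfg$standardize)
    Rec <- sweep(sweep(Rec, 2L, sdev, "*"), 2L, mu, "+")
  out <- t(Rec)
  dimnames(out) <- dimnames(X_block)
  out
}

rbf_gamma_value <- function(Z, gamma) {
  if (is.numeric(gamma)) return(gamma)
  if (gamma == "auto") {
    v <- stats::var(as.vector(Z))
    return(1 / (ncol(Z) * v))
  }
  # median heuristic on pairwise squared distances
  d2 <- as.vector(stats::dist(Z))^2
  med <- stats::median(d2[d2 > 0])
  if (!length(med) || !is.finite(med) || med <= 0) return(NaN)
  1 / med
}

reconstruct_pca <- function(Z, d) {
  n_pts <- nrow(Z)
  full_rank <- min(ncol(Z), n_pts - 1L)
  if (d >= full_rank) return(Z)         # identity projection, exact
  pr <- stats::prcomp(Z, center = TRUE, scale. = FALSE, rank. = d)
  k <- min(d, ncol(pr$rotation))
  scores <- pr$x[, seq_len(k), drop = FALSE]
  scores %*% t(pr$rotation[, seq_len(k), drop = FALSE]) +
    matrix(pr$center, n_pts, ncol(Z), byrow = TRUE)
}

reconstruct_kpca <- function(Z, d, gamma, alpha) {
  d_eff <- min(d, nrow(Z) - 1L)
  kp <- kernlab::kpca(Z, kernel = "rbfdot", kpar = list(sigma = gamma),
                      features = d_eff)
  coords <- kernlab::rotated(kp)        # s x d' kernel-space coordinates
  Cc <- scale(coords, center = TRUE, scale = FALSE)
  ybar <- colMeans(Z)
  Yc <- sweep(Z, 2L, ybar, "-")
  W <- solve(crossprod(Cc) + diag(alpha, ncol(Cc)), crossprod(Cc, Yc))
  sweep(Cc %*% W, 2L, ybar, "+")
}

#' Per-feature reconstruction error
#'
#' The error of feature `i` is the sum (or mean, per `cfg`) over samples
#' of squared differences between observed and reconstructed values:
#' \eqn{r(X, i) = \sum_s (x_{is} - \hat{x}_{is})^2}.
#'
#' @param X_block observed matrix (features x samples).
#' @param X_hat reconstruction with identical dimensions and dimnames.
#' @param aggregation `"sum"` (default) or `"mean"` over samples.
#' @return named non-negative numeric vector, one entry per feature.
#' @export
featurewise_reconstruction_error <- function(X_block, X_hat,
                                             aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  if (!identical(dim(X_block), dim(X_hat)))
    stop("observed and reconstructed matrices differ in shape", call. = FALSE)
  if (!identical(dimnames(X_block), dimnames(X_hat)))
    stop("observed and reconstructed matrices differ in dimnames",
         call. = FALSE)
  res2 <- (X_block - X_hat)^2
  if (aggregation == "sum") rowSums(res2) else rowMeans(res2)
}

# One-call convenience used by the scoring layer.
reconstruction_error_for <- function(X_block, cfg) {
  featurewise_reconstruction_error(X_block, fit_reconstruct(X_block, cfg),
                                   aggregation = cfg$error_aggregation)
}
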