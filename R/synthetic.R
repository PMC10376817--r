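# Synthetic expression-like data with planted class structure: the
# test-bed standing in for many-feature / few-sample gene-expression
# cohorts. Features are drawn block-wise from equicorrelated Gaussians
# (blocks are the recoverable feature clusters); a subset of features
# receives class-conditional mean shifts (the planted biomarkers).

#' Synthetic data specification
#'
#' @param n_features number of features (genes), default 500.
#' @param n_samples number of samples, default 200.
#' @param n_classes number of classes, default 2.
#' @param n_informative number of planted class-informative features,
#'   default 20.
#' @param effect_size class-mean shift in units of `noise_sd` between the
#'   extreme classes (binary: classes sit at -/+ `effect_size/2`),
#'   default 2.
#' @param n_blocks number of correlated feature blocks, default 5.
#' @param within_block_correlation equicorrelation rho inside a block,
#'   in `[0, 1)`, default 0.6.
#' @param noise_sd marginal standard deviation of every feature, default 1.
#' @param zero_inflation_fraction probability that an entry is masked to
#'   exactly 0 after the Gaussian draw (exercises the zero filter),
#'   default 0.
#' @param seed integer RNG seed; same seed, same matrix.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_features = 500L,
                           n_samples = 200L,
                           n_classes = 2L,
                           n_informative = 20L,
                           effect_size = 2,
                           n_blocks = 5L,
                           within_block_correlation = 0.6,
                           noise_sd = 1,
                           zero_inflation_fraction = 0,
                           seed = 1L) {
  stopifnot(n_features >= 1L, n_samples >= 2L, n_classes >= 2L,
            n_informative >= 0L, n_informative <= n_features,
            n_blocks >= 1L, n_blocks <= n_features,
            within_block_correlation >= 0, within_block_correlation < 1,
            noise_sd > 0, zero_inflation_fraction >= 0,
            zero_inflation_fraction < 1,
            n_samples >= 2L * n_classes)
  structure(list(n_features = as.integer(n_features),
                 n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 n_blocks = as.integer(n_blocks),
                 within_block_correlation = within_block_correlation,
                 noise_sd = noise_sd,
                 zero_inflation_fraction = zero_inflation_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression matrix with planted structure
#'
#' Features are drawn block-wise from a multivariate normal with
#' equicorrelation rho inside each block and independence across blocks
#' (implemented through a shared per-sample block factor:
#' `x = noise_sd * (sqrt(rho) z_block + sqrt(1 - rho) eps)`), so every
#' feature has marginal variance `noise_sd^2`. A random subset of
#' `n_informative` features additionally receives a class-conditional
#' mean shift, spaced evenly across classes and spanning
#' `effect_size * noise_sd` between the extreme classes. Optional
#' zero-inflation masks entries to exactly 0 afterwards. Class labels are
#' balanced and shuffled. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `X` (expression matrix, features x samples), `y`
#'   (factor of class labels named by sample), and `truth`: list with
#'   `informative` (planted feature ids), `block` (named integer, block
#'   membership per feature), `class` (= `y`), and `spec`.
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_features; s <- spec$n_samples
  l <- spec$n_classes; rho <- spec$within_block_correlation

  feature_ids <- sprintf("gene_%04d", seq_len(n))
  sample_ids <- sprintf("sample_%04d", seq_len(s))

  # near-equal block sizes summing to n_features
  sizes <- rep(n %/% spec$n_blocks, spec$n_blocks)
  extra <- n %% spec$n_blocks
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  block_of <- rep(seq_len(spec$n_blocks), sizes)

  out <- withr::with_seed(spec$seed, {
    # balanced, shuffled labels
    cls <- sample(rep_len(seq_len(l), s))
    # evenly spaced class shifts spanning effect_size * noise_sd
    shifts <- (seq_len(l) - (l + 1) / 2) / ((l - 1) / 2) *
      (spec$effect_size / 2) * spec$noise_sd

    Zb <- matrix(stats::rnorm(spec$n_blocks * s), spec$n_blocks, s)
    Eps <- matrix(stats::rnorm(n * s), n, s)
    X <- spec$noise_sd * (sqrt(rho) * Zb[block_of, , drop = FALSE] +
                            sqrt(1 - rho) * Eps)

    informative <- if (spec$n_informative > 0L)
      sort(sample.int(n, spec$n_informative)) else integer(0)
    if (length(informative))
      X[informative, ] <- X[informative, ] +
        matrix(shifts[cls], length(informative), s, byrow = TRUE)

    if (spec$zero_inflation_fraction > 0) {
      mask <- matrix(stats::runif(n * s) < spec$zero_inflation_fraction,
                     n, s)
      X[mask] <- 0
    }
    list(X = X, cls = cls, informative = informative)
  })

  X <- out$X
  dimnames(X) <- list(feature_ids, sample_ids)
  y <- stats::setNames(factor(paste0("class_", out$cls),
                              levels = paste0("class_", seq_len(l))),
                       sample_ids)
  truth <- list(informative = feature_ids[out$informative],
                block = stats::setNames(block_of, feature_ids),
                class = y,
                spec = spec)
  list(X = X, y = y, truth = truth)
}

#' Write a synthetic dataset to delimited text
#'
#' Writes `<prefix>_matrix.tsv` (features x samples with an id column),
#' `<prefix>_labels.tsv` (`sample_id`, `label`) and `<prefix>_truth.tsv`
#' (`feature_id`, `block`, `informative`).
#'
#' @param data list returned by [generate_expression()].
#' @param prefix output path prefix.
#' @return invisibly, the three paths written.
#' @export
write_synthetic <- function(data, prefix) {
  mpath <- paste0(prefix, "_matrix.tsv")
  lpath <- paste0(prefix, "_labels.tsv")
  tpath <- paste0(prefix, "_truth.tsv")
  utils::write.table(
    data.frame(feature_id = rownames(data$X), data$X,
               check.names = FALSE, stringsAsFactors = FALSE),
    mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(data$X),
               label = as.character(data$y), stringsAsFactors = FALSE),
    lpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature_id = rownames(data$X),
               block = unname(data$truth$block),
               informative = rownames(data$X) %in% data$truth$informative,
               stringsAsFactors = FALSE),
    tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(mpath, lpath, tpath))
}
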