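---
title: "Class-wise embedding and reconstruction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-wise embedding and reconstruction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clearfpp)
```

## The model

ClearF scores a feature by how much better per-class embeddings explain
it than a pooled embedding does. Write `X ∈ R^{n×s}` for the
feature-by-sample matrix and `Y` for the labels with classes `1..l`.
Samples are the embedded points; features are coordinates. With a
`d`-component embedding fitted to all samples, each feature `i` has a
whole-data reconstruction error `R_X[i]`, the sum over samples of squared
residuals. Splitting samples by class and refitting the embedder on each
block `L_j` gives per-class errors `R_j[i]`, and the score is

$$F_i = R_X[i] - \sum_{j=1}^{l} R_j[i].$$

The intuition is information-theoretic: the reconstruction error of a
good low-dimensional embedding tracks the residual entropy of the data
around its dominant structure, so the difference above behaves like the
reduction in uncertainty about feature `i` obtained by conditioning on
the class — a proxy for mutual information that needs neither
discretization nor density estimation. A feature whose distribution is
stable across classes loses nothing when the pooled fit replaces the
class fits, so its score hovers near zero; a feature whose mean or
structure shifts with the class is cheap to reconstruct within classes
and expensive to reconstruct globally, and scores high.

An assumption worth stating plainly: the class signal must *not* be the
dominant global structure. If one feature's class shift carries more
variance than everything else, the pooled one-component embedding aligns
with it and absorbs the signal, shrinking `R_X` and hence the score.
In realistic expression data the dominant axes are co-expression
programs shared by many genes, and class shifts of individual biomarkers
ride on top of them — exactly the regime the method expects, and the
regime our synthetic generator reproduces through correlated feature
blocks.

### ClearF-one

Fixing `d = 1` removes the bottleneck-size search entirely. With a
single component only the strongest direction of each class's data is
retained, which concentrates the score on features with clean per-class
structure and is markedly more stable when class blocks are small.
`clearf_one_scores()` is literally `clearf_scores()` with
`n_components = 1`; the forwarding is exact.

### ClearF++

One-component embeddings of thousands of features reflect only a few
dominant features. ClearF++ therefore partitions the *features* into `k`
clusters of similar expression profiles, applies ClearF-one within each
cluster, and merges the per-cluster score vectors back into one ranking.
Each feature is scored exactly once, from its own cluster; with `k = 1`
the procedure reduces bitwise (on the linear-PCA path) to ClearF-one.

Merged scores are raw by default: the pseudocode of the procedure says
only "aggregate and rank", and raw concatenation follows it literally.
Because reconstruction-error scales can differ across clusters of
different sizes, `score_normalization` optionally applies per-cluster
z-scoring or per-cluster rank points before merging; we default to
`"none"` and expose the ambiguity rather than hide it.

## Embedders

Two backends, sharing the contract that the reconstruction comes back on
the original scale:

* **`pca`** — rank-`d` truncated projection about the sample mean. When
  the clipped `d` reaches `min(n, s − 1)` the projection is the identity
  and the input is returned exactly; this makes the degenerate cases
  (full-rank `d`, a single feature, a constant feature) score exactly 0
  instead of accumulating float noise.
* **`kpca_rbf`** (default) — kernel PCA with an RBF kernel (via
  `kernlab`), the configuration that historically performed best for
  this score family. Kernel PCA has no native inverse map, so
  reconstruction solves the pre-image problem with ridge regression from
  the kernel-space coordinates back to input space, fitted on the block
  itself (`preimage_ridge_alpha = 1`). This is deterministic and cheap;
  we deliberately avoid iterative pre-image schemes.

Parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `n_components` | 1 | embedding dimension `d`; clipped per block to `min(n, s−1)` with a warning |
| `standardize` | `TRUE` | z-score features with the fitted block's statistics before embedding |
| `rbf_gamma` | `"auto"` | `1 / (n · var(values))` of the block; `"median"` gives the median heuristic |
| `preimage_ridge_alpha` | 1 | ridge penalty of the pre-image map |
| `error_aggregation` | `"sum"` | per-feature error = sum of squared residuals over samples |

Standardization is on by default because RBF kernels are scale-sensitive
and per-block z-scoring keeps class blocks comparable; zero-variance
features are passed through untouched (and therefore reconstruct
exactly). Errors are *sums*, not means, over samples: the score
subtracts class-block errors from whole-data errors, and sums keep both
sides in the same units of total squared error even though the blocks
contain different sample counts. A mean-based option exists for
sensitivity analysis. Clipping (rather than erroring) when a class block
has fewer than `d + 1` samples matters in practice, since per-class
sample counts can be tiny.

## Feature-wise clustering

Features are clustered as points in sample space. By default each
feature's profile is z-scored first (`scale = "profile"`), so clusters
reflect the *shape* of co-variation rather than absolute magnitude —
appropriate when expression levels span orders of magnitude. When
cluster identity is carried by magnitude itself (e.g. constant offsets),
`scale = "none"` clusters raw profiles; the block-recovery tests use
this mode because profile z-scoring is mean/scale-invariant by
construction and erases purely additive separation.

* **k-means** — Lloyd's algorithm with k-means++ seeding, best of 10
  restarts by inertia; deterministic given the seed. Default `k = 5`,
  the count at which k-means-based ClearF++ performs best.
* **DEC** (Deep Embedded Clustering) — (1) pretrain a small symmetric
  autoencoder (tanh hidden layers, linear latent and output) on the
  profiles with squared loss; (2) k-means in latent space initializes
  the centroids; (3) self-train by minimizing `KL(P‖Q)`, where `q_ij` is
  the Student-t similarity of latent point `i` to centroid `j` and
  `p_ij ∝ q_ij²/f_j` is the sharpened target, updating encoder weights
  and centroids jointly with full-batch Adam. The target refreshes every
  `finetune_update_interval` epochs; training stops when fewer than
  `convergence_tol` of the features change cluster between refreshes.
  Default `k = 15`, where DEC-based ClearF++ peaks; the defaults
  (`encoder_dims = input→64→32→10`, 100 pretrain epochs, interval 30,
  tol 0.001, `ν = 1`) are this package's own, scaled to feature counts
  in the hundreds-to-thousands rather than image corpora.

DEC trains on a globally centred/scaled copy of the point matrix (one
scalar mean and sd) so tanh units stay in range on raw magnitudes; a
scalar affine map preserves cluster geometry exactly. Both methods are
seeded and single-threaded, hence bitwise reproducible. Empty clusters
at convergence are reported via `effective_k` with a warning rather than
re-seeded — cluster-count instability is information the user should
see, and very large `k` (50–100) is known to destabilize the procedure.
A singleton cluster scores 0 by the degenerate-dimension rule: a single
component reconstructs one-dimensional data exactly.

The MLP under DEC (and under the reference DNN classifier) is a small
in-package implementation with analytic gradients and Adam; at these
problem sizes a full deep-learning framework would add nothing but a
dependency.

## Evaluation harness

`cross_validate()` reproduces the standard protocol: stratified k-fold
splits (default 10), selector fitted on training samples only, top-`m`
features passed to a classifier, AUC on the held-out fold, averaged over
folds. Stratification keeps per-fold class proportions within one sample
of the global ones — without it, small classes can vanish from folds.
Two classifiers are provided: logistic regression (the fast default) and
the reference four-layer DNN — hidden widths `2m` and `m`, tanh
activations, sigmoid output with cross-entropy, Adam at learning rate
1e-3, 500 full-batch epochs. The DNN's output layer is not part of the
protocol's published description; sigmoid with cross-entropy is the
natural choice for a binary AUC target. Features are z-scored with
training-fold statistics in both classifiers. `compare_selectors()`
reuses one set of fold splits and one selector fit per fold across all
`m` values (a paired design). `aggregate_fold_ranks()` builds the
consensus ranking used for downstream enrichment-style analyses: rank
`r ≤ top_m` earns `top_m − r + 1` points per fold (default `top_m` =
100, i.e. 100 points down to 1), others 0, averaged over folds.

Ranking ties everywhere break lexicographically by feature id, making
every ordering deterministic.

## The synthetic generator

`generate_expression()` emulates the regime the method targets: many
features, few samples, two (or more) balanced classes, background
structure from `n_blocks` equicorrelated Gaussian feature blocks
(`x = σ(√ρ z_block + √(1−ρ) ε)`, marginal variance σ² for every
feature), and `n_informative` planted features with class-conditional
mean shifts spanning `effect_size·σ` between extreme classes. Defaults —
500 features, 200 samples, 20 informative, Δ = 2, 5 blocks, ρ = 0.6 —
are a desk-scale stand-in for public expression cohorts at a
signal-to-noise level (a 2-sd shift) typical of usable biomarkers.
Zero-inflation, applied as a post-hoc mask, exists purely to exercise
the zero-fraction preprocessing filter (features with more than 25%
zeros are removed; "more than" is read strictly, so a feature exactly at
the threshold survives; zero means exactly 0.0, with a configurable
tolerance defaulting to 0).

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: count-based noise (negative binomial
overdispersion), library-size and batch effects, heavy-tailed or
log-normal marginals, nonlinear class boundaries, and correlation
between the informative features and the background blocks beyond the
block they sit in. Inputs are taken as-is (no normalization or log
transform is applied), so users should feed the same normalized scale
they would feed any embedding method.

## Numerical choices and edge cases

* Per-feature error vectors are exact sums of squared residuals;
  the additivity identity `F + Σ_j R_j = R_X` holds to the last bits of
  floating-point rearrangement (tested at 1e-12 relative).
* `d` clipping, zero-variance fallbacks (kernel PCA on a constant block
  falls back to PCA with a warning), full-rank identity shortcut, and
  singleton-cluster zeros are the only special cases; everything else is
  the plain formulas.
* Seeds: each public entry point takes one seed; internal consumers
  (clustering, classifier initialization, permutations) derive child
  seeds deterministically, so runs are bitwise reproducible on the
  linear path and reproducible to eigensolver sign conventions on the
  kernel path.
* Problem sizes in the shipped tests (500×200 scoring runs, 120-feature
  clustering problems, 10-seed replicates) were chosen as the smallest
  sizes at which the statistical properties under test are stable.

## Known limitations

* The score is relative, not calibrated: magnitudes depend on `n`, `s`,
  and the embedder, so only the ranking (or the cross-fold rank
  aggregate) should be compared across runs.
* Multi-class scoring follows the defining sum over class blocks, but
  the evaluation harness is binary (AUC); multi-class evaluation would
  need a different metric.
* The number of clusters `k` remains a user choice. Performance is flat
  over roughly 5–20 clusters and degrades beyond; automatic selection is
  future work.
* Kernel-PCA reconstruction quality depends on the pre-image map; ridge
  pre-images are smooth and can under-fit sharp nonlinear structure.
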