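# Compact multilayer perceptron with manual backpropagation and Adam.
# Internal engine shared by the Deep Embedded Clustering routine and the
# full-batch DNN classifier; sized for the small dense problems this
# package handles (hundreds to a few thousand points).
#
# Conventions: points are rows; layer l maps A_{l-1} (n x d_{l-1}) to
# H_l = A_{l-1} W_l + b_l, followed by tanh or identity per `acts`.

mlp_init <- function(dims, acts) {
  stopifnot(length(acts) == length(dims) - 1L)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]; fan_out <- dims[l + 1L]
    limit <- sqrt(6 / (fan_in + fan_out))       # Glorot uniform
    layers[[l]] <- list(
      W = matrix(stats::runif(fan_in * fan_out, -limit, limit),
                 fan_in, fan_out),
      b = rep(0, fan_out))
  }
  list(layers = layers, dims = dims, acts = acts)
}

mlp_forward <- function(net, X) {
  L <- length(net$layers)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    H <- A[[l]] %*% net$layers[[l]]$W
    H <- sweep(H, 2L, net$layers[[l]]$b, "+")
    A[[l + 1L]] <- if (net$acts[l] == "tanh") tanh(H) else H
  }
  A
}

# dOut: gradient of the loss w.r.t. the network output A[[L+1]].
mlp_backward <- function(net, A, dOut) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    dH <- if (net$acts[l] == "tanh") dA * (1 - A[[l + 1L]]^2) else dA
    grads[[l]] <- list(W = crossprod(A[[l]], dH), b = colSums(dH))
    if (l > 1L) dA <- dH %*% t(net$layers[[l]]$W)
  }
  list(grads = grads,
       dInput = dH %*% t(net$layers[[1L]]$W))
}

adam_init <- function(shapes) {
  lapply(shapes, function(s) list(m = s * 0, v = s * 0))
}

adam_update <- function(theta, grad, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# One Adam step over every layer of a network.
mlp_adam_step <- function(net, grads, opt, lr, t) {
  for (l in seq_along(net$layers)) {
    uw <- adam_update(net$layers[[l]]$W, grads[[l]]$W, opt[[l]]$W, lr, t)
    net$layers[[l]]$W <- uw$theta; opt[[l]]$W <- uw$state
    ub <- adam_update(net$layers[[l]]$b, grads[[l]]$b, opt[[l]]$b, lr, t)
    net$layers[[l]]$b <- ub$theta; opt[[l]]$b <- ub$state
  }
  list(net = net, opt = opt)
}

mlp_opt_init <- function(net) {
  lapply(net$layers, function(ly) list(W = list(m = ly$W * 0, v = ly$W * 0),
                                       b = list(m = ly$b * 0, v = ly$b * 0)))
}

# Train a symmetric autoencoder on P (points x dims) by full-batch Adam on
# mean squared reconstruction error. encoder_dims excludes the input width;
# the last entry is the latent dimension. Hidden layers are tanh; the
# latent and output layers are linear.
train_autoencoder <- function(P, encoder_dims, epochs, lr = 1e-3) {
  D <- ncol(P)
  dims <- c(D, encoder_dims, rev(encoder_dims)[-1L], D)
  n_enc <- length(encoder_dims)
  acts <- c(rep("tanh", n_enc - 1L), "linear",      # encoder, linear latent
            rep("tanh", n_enc - 1L), "linear")      # decoder, linear output
  net <- mlp_init(dims, acts)
  opt <- mlp_opt_init(net)
  n <- nrow(P)
  for (t in seq_len(epochs)) {
    A <- mlp_forward(net, P)
    out <- A[[length(A)]]
    dOut <- 2 * (out - P) / (n * D)
    bk <- mlp_backward(net, A, dOut)
    st <- mlp_adam_step(net, bk$grads, opt, lr, t)
    net <- st$net; opt <- st$opt
  }
  list(net = net, n_encoder_layers = n_enc)
}

# Split a trained autoencoder into its encoder half.
encoder_of <- function(ae) {
  list(layers = ae$net$layers[seq_len(ae$n_encoder_layers)],
       dims = ae$net$dims[seq_len(ae$n_encoder_layers + 1L)],
       acts = ae$net$acts[seq_len(ae$n_encoder_layers)])
}
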