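# Minimal fully-connected networks with manual backpropagation and Adam.
# Dense BLAS matrix products are the whole cost; networks here are small
# (default 2 hidden layers on a 1500-dim DVH state), so base R is adequate.

# He-initialized MLP with ReLU hidden layers and a linear output layer.
# Consumes the current RNG stream (callers seed it).
mlp_init <- function(in_dim, hidden, out_dim) {
  sizes <- c(in_dim, hidden, out_dim)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

# Forward pass. X: batch x in_dim matrix. Returns output and the per-layer
# activations needed for the backward pass.
mlp_forward <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1]] <- X
  A <- X
  for (l in seq_len(L)) {
    Z <- sweep(A %*% net$W[[l]], 2, net$b[[l]], `+`)
    A <- if (l < L) pmax(Z, 0) else Z
    acts[[l + 1]] <- A
  }
  list(out = A, acts = acts)
}

# Backward pass: dOut is dLoss/dOutput (batch x out_dim). Returns gradients
# with the same shapes as the parameters.
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    A_prev <- cache$acts[[l]]
    dW[[l]] <- crossprod(A_prev, delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(net$W[[l]])
      delta <- delta * (cache$acts[[l]] > 0)   # ReLU mask
    }
  }
  list(W = dW, b = db)
}

adam_init <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b), t = 0L)
}

adam_step <- function(net, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (state$mW[[l]] / bc1) /
      (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (state$mb[[l]] / bc1) /
      (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Coerce an environment state (dvh_state or numeric) to the flat observation.
as_state_vector <- function(s) {
  if (inherits(s, "dvh_state")) flatten_state(s) else as.numeric(s)
}
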