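# Internal dense-network primitives. Plain R matrices + OpenBLAS are fast
# enough at the problem sizes this package targets; parameters are kept as
# lists of (W, b) layers so they can be flattened for optimizers and
# finite-difference checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

# add a row vector to every row (column-major recycling; avoids sweep)
add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}

# derivative of ELU from the pre-activation
elu_grad <- function(z) {
  g <- z
  pos <- z > 0
  g[pos] <- 1
  g[!pos] <- exp(z[!pos])
  g
}

# Fan-in scaled Gaussian init (He); draws from the current RNG stream.
mlp_new <- function(sizes) {
  stopifnot(length(sizes) >= 2)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    n_in <- sizes[l]
    n_out <- sizes[l + 1L]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
      b = numeric(n_out)
    )
  }
  layers
}

# Forward pass. X: n x in. Returns out plus the caches backward needs.
# dropout_masks, if supplied, are multiplied onto hidden activations
# (inverted dropout; masks already scaled by 1/keep).
mlp_forward <- function(layers, X, dropout_masks = NULL) {
  L <- length(layers)
  inputs <- vector("list", L)   # input to each layer
  pre <- vector("list", L)      # pre-activations
  A <- X
  for (l in seq_len(L)) {
    inputs[[l]] <- A
    Z <- add_bias(A %*% layers[[l]]$W, layers[[l]]$b)
    pre[[l]] <- Z
    if (l < L) {
      A <- elu(Z)
      if (!is.null(dropout_masks)) A <- A * dropout_masks[[l]]
    } else {
      A <- Z
    }
  }
  list(out = A, inputs = inputs, pre = pre, dropout_masks = dropout_masks)
}

# Backward pass: dOut is dLoss/dOut (n x out). Returns per-layer gradients
# and the gradient w.r.t. the input matrix.
mlp_backward <- function(layers, cache, dOut) {
  L <- length(layers)
  dW <- vector("list", L)
  db <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    dZ <- if (l < L) {
      m <- elu_grad(cache$pre[[l]])
      if (!is.null(cache$dropout_masks)) m <- m * cache$dropout_masks[[l]]
      dA * m
    } else {
      dA
    }
    dW[[l]] <- crossprod(cache$inputs[[l]], dZ)
    db[[l]] <- colSums(dZ)
    dA <- tcrossprod(dZ, layers[[l]]$W)
  }
  list(dW = dW, db = db, dX = dA)
}

# --- Adam optimizer over a flat numeric parameter vector ------------------

adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  theta_new_wd <- if (any(weight_decay > 0)) {
    theta * (1 - lr * weight_decay)  # scalar or per-parameter vector
  } else theta
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta_new_wd - lr * mhat / (sqrt(vhat) + eps)
  list(state = state, theta = theta)
}
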