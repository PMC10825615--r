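# Minimal dense multilayer perceptron with tanh hidden units and a linear
# scalar output, with explicit forward/backward passes. The survival model
# needs custom gradients (a ranking loss through a sort-and-select
# aggregation), so the network is written out rather than fitted with a
# canned regression tool.

mlp_init <- function(sizes) {
  # sizes: c(in, hidden..., out)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    sd <- sqrt(2 / (fan_in + fan_out))
    layers[[l]] <- list(W = matrix(stats::rnorm(fan_in * fan_out, sd = sd),
                                   fan_in, fan_out),
                        b = numeric(fan_out))
  }
  layers
}

# X: n x in. Returns list(out = n-vector (out dim 1) or matrix, cache).
mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  L <- length(layers)
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, `+`)
    acts[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  list(out = acts[[L + 1L]], acts = acts)
}

# dOut: n x out gradient of the loss wrt the network output.
# Returns list(grads = per-layer list(W, b), dX = n x in).
mlp_backward <- function(layers, cache, dOut) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    A_in <- cache$acts[[l]]
    grads[[l]] <- list(W = crossprod(A_in, delta),
                       b = colSums(delta))
    dA_in <- delta %*% t(layers[[l]]$W)
    if (l > 1L) {
      # hidden activation was tanh; derivative 1 - tanh^2 uses the stored
      # post-activation values
      dA_in <- dA_in * (1 - cache$acts[[l]]^2)
    }
    delta_prev <- dA_in
    if (l > 1L) delta <- delta_prev
  }
  list(grads = grads, dX = dA_in)
}

mlp_flatten <- function(layers) {
  unlist(lapply(layers, function(l) c(as.numeric(l$W), l$b)))
}

mlp_unflatten <- function(layers, theta) {
  pos <- 0L
  for (l in seq_along(layers)) {
    nw <- length(layers[[l]]$W)
    layers[[l]]$W[] <- theta[pos + seq_len(nw)]; pos <- pos + nw
    nb <- length(layers[[l]]$b)
    layers[[l]]$b[] <- theta[pos + seq_len(nb)]; pos <- pos + nb
  }
  layers
}

# Adam state and update over a flat parameter vector.
adam_init <- function(n_par, lr = 1e-2, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = numeric(n_par), v = numeric(n_par), t = 0L,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(state, theta, grad) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  list(theta = theta - state$lr * mhat / (sqrt(vhat) + state$eps),
       state = state)
}
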