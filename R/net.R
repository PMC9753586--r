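# Minimal fully-connected network with manual backpropagation and Adam.
# Kept internal: the user-facing surface is train_embedding()/predict().

.net_init <- function(input_dim, hidden, output_dim) {
  dims <- c(input_dim, hidden, output_dim)
  layers <- vector("list", length(dims) - 1L)
  for (i in seq_along(layers)) {
    fan_in <- dims[i]
    # Xavier/Glorot scaling keeps tanh activations in range
    layers[[i]] <- list(
      w = matrix(stats::rnorm(dims[i] * dims[i + 1L], sd = sqrt(1 / fan_in)),
                 dims[i], dims[i + 1L]),
      b = rep(0, dims[i + 1L]))
  }
  layers
}

# forward pass; returns output and cached pre-/post-activations for backprop
.net_forward <- function(layers, x) {
  n_layer <- length(layers)
  acts <- vector("list", n_layer + 1L)
  acts[[1L]] <- x
  h <- x
  for (i in seq_len(n_layer)) {
    z <- sweep(h %*% layers[[i]]$w, 2, layers[[i]]$b, "+")
    h <- if (i < n_layer) tanh(z) else z # linear output layer
    acts[[i + 1L]] <- h
  }
  list(output = h, acts = acts)
}

# gradient of a scalar loss wrt all parameters, given dL/d(output)
.net_backward <- function(layers, acts, d_out) {
  n_layer <- length(layers)
  grads <- vector("list", n_layer)
  delta <- d_out
  for (i in rev(seq_len(n_layer))) {
    if (i < n_layer) delta <- delta * (1 - acts[[i + 1L]]^2) # tanh'
    grads[[i]] <- list(w = crossprod(acts[[i]], delta),
                       b = colSums(delta))
    if (i > 1L) delta <- delta %*% t(layers[[i]]$w)
  }
  grads
}

.adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mw = 0 * l$w, vw = 0 * l$w, mb = 0 * l$b, vb = 0 * l$b))
}

.adam_step <- function(layers, grads, state, t, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    s <- state[[i]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layers[[i]]$w <- layers[[i]]$w -
      lr * (s$mw / bc1) / (sqrt(s$vw / bc2) + eps)
    layers[[i]]$b <- layers[[i]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}
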