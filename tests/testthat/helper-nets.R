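# Seeded micro-networks and hand-built toys shared across the suite.

# Two feedback (relu) layers, 8 + 4 = 12 gates: small enough for the
# exhaustive gate-search oracle.
micro_net <- function(seed) {
  net_build(list(conv_layer(3L, 2L), relu_layer(), flatten_layer(),
                 dense_layer(4L), relu_layer(), dense_layer(3L),
                 softmax_layer()),
            input_shape = c(4L, 4L, 1L), seed = seed, init_scale = 2)
}

# Single feedback layer (8 gates): the per-layer objective is separable, so
# the greedy optimizers must match the exhaustive optimum.
micro_net_single <- function(seed) {
  net_build(list(conv_layer(3L, 2L), relu_layer(), flatten_layer(),
                 dense_layer(3L), softmax_layer()),
            input_shape = c(4L, 4L, 1L), seed = seed, init_scale = 2)
}

rand_image <- function(seed, dims = c(4L, 4L)) {
  withr::with_seed(seed, matrix(stats::runif(prod(dims), -1, 1),
                                dims[1L], dims[2L]))
}

# Overwrite a dense layer's parameters in place.
set_dense <- function(net, i, W, b = NULL) {
  W <- matrix(W, net$layers[[i]]$din, net$layers[[i]]$units)
  net$params[[i]]$W <- W
  net$params[[i]]$b <- if (is.null(b)) numeric(net$layers[[i]]$units) else b
  net
}

# Zero every bias (so gated logits are exactly linear in any layer's gated
# outputs).
zero_biases <- function(net) {
  for (i in seq_along(net$params)) {
    if (!is.null(net$params[[i]])) net$params[[i]]$b[] <- 0
  }
  net
}

# Central finite differences of f at x (vectorized over coordinates).
fd_gradient <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
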