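#' Build a convolutional network
#'
#' Chains a list of layer specifications from an input shape, validates that
#' adjacent layers agree on dimensions and channels, precomputes the gather
#' indices used by convolution and pooling, and draws initial parameters from
#' a seeded zero-mean uniform distribution scaled by fan-in. Rebuilding with
#' the same seed is bit-identical.
#'
#' @param layers List of layer specifications from [conv_layer()] and friends.
#' @param input_shape Integer vector `c(height, width, channels)`; a length-2
#'   vector implies a single channel.
#' @param seed Integer seed for parameter initialization (mandatory).
#' @param init_scale Multiplier on the `1/sqrt(fan_in)` uniform half-width.
#' @return An object of class `"fbcnn_net"`: fields `layers` (specs augmented
#'   with resolved dimensions), `params` (per-layer `W`/`b` or `NULL`),
#'   `input_shape`.
#' @examples
#' net <- net_build(list(conv_layer(3, 2), relu_layer(), flatten_layer(),
#'                       dense_layer(4), softmax_layer()),
#'                  input_shape = c(6, 6, 1), seed = 1)
#' net
#' @export
net_build <- function(layers, input_shape, seed, init_scale = 1) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(input_shape) == 2L) input_shape <- c(input_shape, 1L)
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1L))
  input_shape <- as.integer(input_shape)
  dims <- input_shape            # current (H, W, C); NA marks flattened
  flat <- FALSE
  prev_kind <- "input"
  out <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (!inherits(ly, "fbcnn_layer")) stop("layers[[", i, "]] is not a layer spec")
    ly$din <- if (flat) dims else prod(dims)
    ly$in_dims <- if (flat) NULL else dims
    pair <- sprintf("%s -> %s (layer %d)", prev_kind, ly$kind, i)
    if (ly$kind %in% c("conv", "maxpool") && flat)
      stop("shape chain mismatch at ", pair, ": spatial layer after flatten")
    if (ly$kind == "conv") {
      if (!is.null(ly$in_channels) && ly$in_channels != dims[3L])
        stop("shape chain mismatch at ", pair, ": declared in_channels ",
             ly$in_channels, " != ", dims[3L])
      ly$ix <- .conv_indices(dims[1L], dims[2L], dims[3L], ly$kernel_size, ly$padding)
      dims <- c(ly$ix$Ho, ly$ix$Wo, ly$out_channels)
    } else if (ly$kind == "maxpool") {
      ly$ix <- .pool_indices(dims[1L], dims[2L], dims[3L], ly$window, ly$stride)
      dims <- c(ly$ix$Ho, ly$ix$Wo, dims[3L])
    } else if (ly$kind == "flatten") {
      if (flat) stop("shape chain mismatch at ", pair, ": input already flat")
      dims <- prod(dims); flat <- TRUE
    } else if (ly$kind == "dense") {
      if (!flat) { dims <- prod(dims); flat <- TRUE }  # implicit flatten
      if (!is.null(ly$in_dim) && ly$in_dim != dims)
        stop("shape chain mismatch at ", pair, ": declared in_dim ",
             ly$in_dim, " != ", dims)
      dims <- ly$units
    }
    ly$dout <- if (flat) dims else prod(dims)
    ly$out_dims <- if (flat) NULL else dims
    out[[i]] <- ly
    prev_kind <- ly$kind
  }
  net <- structure(list(layers = out, params = NULL,
                        input_shape = input_shape, seed = as.integer(seed)),
                   class = "fbcnn_net")
  net$params <- .init_params(net, seed, init_scale)
  net
}

.init_params <- function(net, seed, init_scale) {
  .with_seed(seed, lapply(net$layers, function(ly) {
    if (ly$kind == "conv") {
      a <- init_scale / sqrt(ly$ix$Q)
      list(W = matrix(stats::runif(ly$ix$Q * ly$out_channels, -a, a),
                      ly$ix$Q, ly$out_channels),
           b = numeric(ly$out_channels))
    } else if (ly$kind == "dense") {
      a <- init_scale / sqrt(ly$din)
      list(W = matrix(stats::runif(ly$din * ly$units, -a, a),
                      ly$din, ly$units),
           b = numeric(ly$units))
    } else NULL
  }))
}

.as_row <- function(net, image) {
  x <- as.numeric(image)
  if (length(x) != prod(net$input_shape))
    stop("input has ", length(x), " values; model expects ",
         paste(net$input_shape, collapse = "x"))
  matrix(x, 1L)
}

# Batched forward pass; X is B x din. Returns final output and (optionally)
# per-layer caches and inputs for backpropagation.
.net_forward_mat <- function(net, X, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$layers))
  inputs <- if (keep_cache) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    if (keep_cache) inputs[[i]] <- X
    st <- .layer_forward(net$layers[[i]], net$params[[i]], X, keep_cache = keep_cache)
    X <- st$Y
    if (keep_cache) caches[[i]] <- st$cache
  }
  list(out = X, caches = caches, inputs = inputs)
}

# Backpropagate dOut through cached layers starting at layer `from` (default
# the last). Returns input gradient and per-layer parameter gradients.
.net_backward_mat <- function(net, fw, dOut, from = length(net$layers)) {
  grads <- vector("list", length(net$layers))
  dY <- dOut
  for (i in rev(seq_len(from))) {
    bk <- .layer_backward(net$layers[[i]], net$params[[i]], fw$caches[[i]], dY)
    if (!is.null(bk$dW)) grads[[i]] <- list(dW = bk$dW, db = bk$db)
    dY <- bk$dX
  }
  list(dX = dY, grads = grads)
}

#' Forward pass with full activation tracing
#'
#' Runs one image through the network and records, for every layer, its input
#' and output, the binary rectifier pattern (pre-activation strictly positive)
#' of every ReLU layer, and the argmax position of every max-pooling window.
#' The trace is the raw material for feedback gates ([gates_from_trace()]) and
#' for input-space gradients ([net_input_gradient()]).
#'
#' @param net An `"fbcnn_net"`.
#' @param image Numeric array/matrix matching `net$input_shape`.
#' @return Class `"fbcnn_trace"`: `output` (final layer output vector),
#'   `layers` (per-layer list with `x`, `y`, and `mask`/`arg` where relevant),
#'   plus cached intermediates for backpropagation.
#' @export
net_forward <- function(net, image) {
  X <- .as_row(net, image)
  fw <- .net_forward_mat(net, X, keep_cache = TRUE)
  per <- lapply(seq_along(net$layers), function(i) {
    ly <- net$layers[[i]]
    ent <- list(kind = ly$kind,
                x = as.numeric(fw$inputs[[i]]),
                y = if (i < length(net$layers)) as.numeric(fw$inputs[[i + 1L]])
                    else as.numeric(fw$out))
    if (ly$kind == "relu") ent$mask <- as.numeric(fw$caches[[i]]$mask)
    if (ly$kind == "maxpool") ent$arg <- fw$caches[[i]]$arg
    ent
  })
  structure(list(output = as.numeric(fw$out), layers = per, fw = fw),
            class = "fbcnn_trace")
}

#' Gradient of one output neuron with respect to the input image
#'
#' Backpropagates from a chosen output neuron through a recorded forward
#' trace; rectifier and pooling gradients are routed by the trace's stored
#' patterns and argmax switches.
#'
#' @param net An `"fbcnn_net"`.
#' @param trace Trace from [net_forward()] on the same model.
#' @param target_index 1-based index of the output neuron.
#' @param from `"output"` differentiates the network's final output (through
#'   the softmax if present); `"logit"` differentiates the pre-softmax class
#'   score, the target used by the feedback machinery.
#' @return Numeric array shaped like the input image.
#' @export
net_input_gradient <- function(net, trace, target_index,
                               from = c("output", "logit")) {
  from <- match.arg(from)
  n <- length(net$layers)
  last <- if (from == "logit" && net$layers[[n]]$kind == "softmax") n - 1L else n
  dout <- net$layers[[last]]$dout
  if (target_index < 1L || target_index > dout)
    stop("target_index ", target_index, " out of range 1..", dout)
  dOut <- matrix(0, 1L, dout)
  dOut[1L, target_index] <- 1
  bk <- .net_backward_mat(net, trace$fw, dOut, from = last)
  array(as.numeric(bk$dX), dim = net$input_shape)
}

#' @export
print.fbcnn_net <- function(x, ...) {
  cat("Convolutional network, input",
      paste(x$input_shape, collapse = "x"), "\n")
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    desc <- switch(ly$kind,
      conv = sprintf("conv %dx%d, %d -> %d channels (%s)", ly$kernel_size,
                     ly$kernel_size, ly$in_dims[3L], ly$out_channels, ly$padding),
      maxpool = sprintf("maxpool %dx%d stride %d", ly$window, ly$window, ly$stride),
      dense = sprintf("dense %d -> %d", ly$din, ly$units),
      ly$kind)
    outd <- if (is.null(ly$out_dims)) ly$dout else paste(ly$out_dims, collapse = "x")
    cat(sprintf("  %2d. %-28s -> %s\n", i, desc, outd))
  }
  np <- sum(vapply(x$params, function(p) if (is.null(p)) 0L else length(p$W) + length(p$b), 0L))
  cat("  parameters:", np, "\n")
  invisible(x)
}

#' Save / load a network
#'
#' Single-file serialization of layer specifications and parameter tensors;
#' the round trip is bit-exact.
#'
#' @param net An `"fbcnn_net"`.
#' @param path File path.
#' @return `net_load` returns the network; `net_save` returns `path`
#'   invisibly.
#' @export
net_save <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname net_save
#' @export
net_load <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "fbcnn_net")) stop("file does not contain an fbcnn network")
  net
}

# Index positions (in net$layers) of the feedback (ReLU) and pooling layers.
.relu_layers <- function(net) which(vapply(net$layers, `[[`, "", "kind") == "relu")
.pool_layers <- function(net) which(vapply(net$layers, `[[`, "", "kind") == "maxpool")
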