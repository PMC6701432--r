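# Gate-switch reinterpretation of the network and the two greedy feedback
# optimizers.
#
# Every rectifier neuron carries a binary feedback gate z; the rectifier's
# max(0, x) is realized purely by the switch (the pre-activation is passed
# through iff z = 1, else 0), and every max-pooling layer reads the value at
# its recorded feedforward argmax switch instead of recomputing the maximum.
# With all switches frozen the image -> class-logit map is affine, which is
# what makes per-layer greedy gate updates exact.

#' Feedback gates from a forward trace
#'
#' The feedforward gate state: a rectifier gate is open iff its
#' pre-activation is strictly positive (zero pre-activations give closed
#' gates), and the max-pool switches are the argmax positions recorded in the
#' trace.
#'
#' @param trace A trace from [net_forward()].
#' @return Object of class `"fbcnn_gates"`: `relu` (per-layer 0/1 vectors at
#'   rectifier positions), `pool` (per-layer argmax switch vectors),
#'   `provenance`.
#' @export
gates_from_trace <- function(trace) {
  stopifnot(inherits(trace, "fbcnn_trace"))
  n <- length(trace$layers)
  relu <- vector("list", n); pool <- vector("list", n)
  for (i in seq_len(n)) {
    if (trace$layers[[i]]$kind == "relu") relu[[i]] <- trace$layers[[i]]$mask
    if (trace$layers[[i]]$kind == "maxpool") pool[[i]] <- trace$layers[[i]]$arg
  }
  structure(list(relu = relu, pool = pool, provenance = "feedforward"),
            class = "fbcnn_gates")
}

.check_gates <- function(net, gates) {
  if (!inherits(gates, "fbcnn_gates")) stop("gates must be an fbcnn_gates object")
  for (i in .relu_layers(net)) {
    z <- gates$relu[[i]]
    if (is.null(z) || length(z) != net$layers[[i]]$dout)
      stop("gate mask for layer ", i, " has wrong shape")
    if (any(z != 0 & z != 1)) stop("gate values must be 0 or 1 (layer ", i, ")")
  }
  for (i in .pool_layers(net)) {
    a <- gates$pool[[i]]
    if (is.null(a) || length(a) != net$layers[[i]]$ix$P)
      stop("pool switches for layer ", i, " have wrong shape")
    if (any(a < 1L | a > net$layers[[i]]$ix$W2))
      stop("pool switch outside its window (layer ", i, ")")
  }
  invisible(TRUE)
}

.layer_gate <- function(layer, gates, i) {
  if (layer$kind == "relu") gates$relu[[i]]
  else if (layer$kind == "maxpool") gates$pool[[i]]
  else NULL
}

# Forward under frozen switches; single image (B = 1).
.gated_forward_mat <- function(net, X, gates, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$layers))
  inputs <- if (keep_cache) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    if (keep_cache) inputs[[i]] <- X
    st <- .layer_forward(net$layers[[i]], net$params[[i]], X,
                         gate = .layer_gate(net$layers[[i]], gates, i),
                         keep_cache = keep_cache)
    X <- st$Y
    if (keep_cache) caches[[i]] <- st$cache
  }
  list(out = X, caches = caches, inputs = inputs)
}

# Backpropagate through the gated network from layer `from` down to (and
# excluding) layer `to`; returns the gradient w.r.t. layer `to`'s output
# (to = 0 gives the input-image gradient).
.gated_backward <- function(net, fw, gates, dOut, from, to = 0L) {
  dY <- dOut
  if (from <= to) return(dY)
  for (i in seq(from, to + 1L)) {
    bk <- .layer_backward(net$layers[[i]], net$params[[i]], fw$caches[[i]], dY,
                          gate = .layer_gate(net$layers[[i]], gates, i))
    dY <- bk$dX
  }
  dY
}

# Index of the pre-softmax (class logit) layer.
.logit_layer <- function(net) {
  n <- length(net$layers)
  if (net$layers[[n]]$kind == "softmax") n - 1L else n
}

#' Forward pass with explicit feedback gates
#'
#' Runs one image through the network with every rectifier replaced by its
#' binary switch (pre-activation passed iff the gate is 1) and every
#' max-pooling layer frozen at the supplied switch positions. With the
#' feedforward gates of [gates_from_trace()] this reproduces [net_forward()]
#' exactly.
#'
#' @param net An `"fbcnn_net"`.
#' @param image Input image matching `net$input_shape`.
#' @param gates An `"fbcnn_gates"` object shaped for this model.
#' @return List with `output` (final network output), `logit` (pre-softmax
#'   class scores), and `trace` (gated activation trace).
#' @export
gated_forward <- function(net, image, gates) {
  .check_gates(net, gates)
  X <- .as_row(net, image)
  fw <- .gated_forward_mat(net, X, gates, keep_cache = TRUE)
  ll <- .logit_layer(net)
  logit <- if (ll < length(net$layers)) as.numeric(fw$inputs[[ll + 1L]])
           else as.numeric(fw$out)
  list(output = as.numeric(fw$out), logit = logit, fw = fw)
}

#' Linearize the network at frozen switch states
#'
#' With all rectifier gates and pooling switches frozen, the map from the
#' input image to any class logit is affine, so the first-order expansion
#' around the anchor image is exact and gradients are available in closed
#' form at any interior layer.
#'
#' @param net An `"fbcnn_net"`.
#' @param image Anchor image.
#' @param gates Frozen gate state.
#' @return Object of class `"fbcnn_linnet"` supporting [lin_value()],
#'   [contributions()] and input-gradient queries.
#' @export
linearize <- function(net, image, gates) {
  .check_gates(net, gates)
  structure(list(net = net, anchor = image, gates = gates),
            class = "fbcnn_linnet")
}

#' Evaluate the linearized (frozen-switch) network
#'
#' @param lin An `"fbcnn_linnet"` from [linearize()].
#' @param image Input at which to evaluate; defaults to the anchor.
#' @param target_index Optional 1-based logit index; when `NULL` the full
#'   logit vector is returned.
#' @export
lin_value <- function(lin, image = NULL, target_index = NULL) {
  if (is.null(image)) image <- lin$anchor
  gf <- gated_forward(lin$net, image, lin$gates)
  if (is.null(target_index)) gf$logit else gf$logit[target_index]
}

#' Contribution weights of a feedback layer
#'
#' The contribution weight of a feedback (rectifier) neuron is the partial
#' derivative of the target logit with respect to that neuron's gated output,
#' taken through the currently gated pathways above the layer (equivalently,
#' the sum over all connecting pathways of the products of path weights).
#' The neuron's own gate is excluded, so the weight measures what the neuron
#' would contribute if its gate were open.
#'
#' @param lin An `"fbcnn_linnet"`.
#' @param layer_id Index (in `net$layers`) of a rectifier layer.
#' @param target_index 1-based index of the target logit.
#' @return Object of class `"fbcnn_contrib"`: `layer_id`, `alpha` (numeric
#'   vector shaped like the layer output), and `x` (the feedback neurons'
#'   input under the current gates).
#' @export
contributions <- function(lin, layer_id, target_index) {
  net <- lin$net
  if (layer_id < 1L || layer_id > length(net$layers) ||
      net$layers[[layer_id]]$kind != "relu")
    stop("layer ", layer_id, " is not a feedback (relu) layer")
  ll <- .logit_layer(net)
  X <- .as_row(net, lin$anchor)
  fw <- .gated_forward_mat(net, X, lin$gates, keep_cache = TRUE)
  dout <- net$layers[[ll]]$dout
  if (target_index < 1L || target_index > dout)
    stop("target_index out of range 1..", dout)
  dOut <- matrix(0, 1L, dout)
  dOut[1L, target_index] <- 1
  alpha <- .gated_backward(net, fw, lin$gates, dOut, from = ll, to = layer_id)
  structure(list(layer_id = layer_id, alpha = as.numeric(alpha),
                 x = as.numeric(fw$inputs[[layer_id]])),
            class = "fbcnn_contrib")
}

#' Feedback objective (gated target logit)
#'
#' The value being maximized by the greedy optimizers: the target class logit
#' of the frozen-switch network, equal to the sum over any feedback layer of
#' contribution weight x gate x neuron input, plus the bias terms carried by
#' the fixed affine maps. With feedforward gates it equals the plain forward
#' target logit.
#'
#' @param net An `"fbcnn_net"` or `"fbcnn_linnet"`.
#' @param image Input image (ignored when `net` is a linearized network).
#' @param gates Gate state.
#' @param target_index 1-based logit index.
#' @return Scalar objective value.
#' @export
feedback_objective <- function(net, image, gates, target_index) {
  if (inherits(net, "fbcnn_linnet")) {
    image <- net$anchor
    net <- net$net
  }
  gated_forward(net, image, gates)$logit[target_index]
}

#' Define a feedback optimization problem
#'
#' @param net Trained or untrained `"fbcnn_net"` (or a fitted `"fbcnn"`, whose
#'   network is used).
#' @param image Input image.
#' @param target_index 1-based index of the target neuron (pre-softmax class
#'   logit) whose activation is to be maximized.
#' @param lambda Sparsity weight of the original regularized objective;
#'   carried for interface stability but unused by the greedy solvers, which
#'   work on the unregularized linearized objective.
#' @param max_sweeps Maximum number of full passes over the feedback layers.
#' @param tolerance Absolute objective improvement under which a sweep counts
#'   as converged.
#' @return Object of class `"fbcnn_problem"`.
#' @export
feedback_problem <- function(net, image, target_index, lambda = 0,
                             max_sweeps = 10L, tolerance = 1e-9) {
  if (inherits(net, "fbcnn")) net <- net$net
  stopifnot(inherits(net, "fbcnn_net"))
  if (max_sweeps < 1L) stop("max_sweeps must be >= 1")
  ll <- .logit_layer(net)
  if (target_index < 1L || target_index > net$layers[[ll]]$dout)
    stop("target_index out of range 1..", net$layers[[ll]]$dout)
  structure(list(net = net, image = image, target_index = as.integer(target_index),
                 lambda = lambda, max_sweeps = as.integer(max_sweeps),
                 tolerance = tolerance),
            class = "fbcnn_problem")
}

# Shared greedy engine. At each layer visit the contribution weights are
# computed fresh under the gate state entering the visit, and the layer's
# gates are set to the exact per-layer argmax of the affine objective:
# open iff alpha * x > 0 strictly (a zero contribution cannot raise the
# objective, so ties close). Because the frozen-switch objective restricted
# to one layer's gates is sum(alpha * z * x) + const, every update is
# non-decreasing and the trajectory converges on the finite gate lattice.
.feedback_run <- function(problem, order = c("topdown", "bottomup"),
                          provenance) {
  order <- match.arg(order)
  net <- problem$net; image <- problem$image; tg <- problem$target_index
  trace <- net_forward(net, image)
  gates <- gates_from_trace(trace)
  relus <- .relu_layers(net)
  visit <- if (order == "topdown") rev(relus) else relus
  S <- feedback_objective(net, image, gates, tg)
  initial <- S
  traj <- numeric(0)
  converged <- FALSE
  sweeps <- 0L
  for (sweep in seq_len(problem$max_sweeps)) {
    changed <- FALSE
    S_enter <- S
    for (l in visit) {
      cw <- contributions(linearize(net, image, gates), l, tg)
      znew <- as.numeric(cw$alpha * cw$x > 0)
      if (any(znew != gates$relu[[l]])) {
        gates$relu[[l]] <- znew
        changed <- TRUE
      }
      S <- feedback_objective(net, image, gates, tg)
      if (!is.finite(S)) stop("non-finite feedback objective at layer ", l)
      traj <- c(traj, S)
    }
    sweeps <- sweep
    if (!changed || (S - S_enter) < problem$tolerance) {
      converged <- TRUE
      break
    }
  }
  gates$provenance <- provenance
  closed <- vapply(relus, function(l) mean(gates$relu[[l]] == 0), 0)
  names(closed) <- paste0("layer", relus)
  structure(list(gates = gates, initial_objective = initial,
                 objective_trajectory = traj, sweeps_used = sweeps,
                 converged = converged, closed_fraction = closed,
                 target_index = tg, algorithm = provenance),
            class = "fbcnn_feedback")
}

#' Greedy feedback optimizers
#'
#' `feedback_recovery()` sweeps the feedback layers from the top (nearest the
#' output) downward, recomputing contribution weights under the current gates
#' before each layer update; `feedback_selective()` sweeps from the bottom
#' (nearest the input) upward, with contribution weights computed once per
#' layer visit under the gate state entering that visit. Both update a
#' layer's gates to keep exactly the neurons whose contribution
#' (weight x input) is strictly positive, so the objective trajectory is
#' non-decreasing and the sweeps terminate on the finite set of gate states.
#'
#' @param problem An `"fbcnn_problem"` from [feedback_problem()].
#' @return Object of class `"fbcnn_feedback"`: final `gates`,
#'   `initial_objective`, `objective_trajectory` (one value per layer-update
#'   step), `sweeps_used`, `converged`, `closed_fraction` per feedback layer.
#' @export
feedback_recovery <- function(problem) {
  .feedback_run(problem, "topdown", "fr")
}

#' @rdname feedback_recovery
#' @export
feedback_selective <- function(problem) {
  .feedback_run(problem, "bottomup", "fs")
}

#' Exhaustive gate-search oracle
#'
#' Enumerates all 2^n rectifier-gate configurations (pooling switches frozen
#' at their feedforward positions) and returns the configuration maximizing
#' the frozen-switch objective. Intended as a test oracle for the greedy
#' optimizers on micro-networks; refuses problems with more gates than
#' `gate_budget`. Ties are broken toward the lexicographically smallest gate
#' vector (layers in network order, first gate most significant).
#'
#' @param problem An `"fbcnn_problem"`.
#' @param gate_budget Maximum total number of rectifier gates (<= 16).
#' @return List with `gates`, `objective`, and `n_gates`.
#' @export
brute_force_gate_search <- function(problem, gate_budget = 16L) {
  net <- problem$net
  relus <- .relu_layers(net)
  sizes <- vapply(relus, function(l) as.integer(net$layers[[l]]$dout), 0L)
  n <- sum(sizes)
  if (n > gate_budget)
    stop("problem has ", n, " gates, exceeding the budget of ", gate_budget)
  trace <- net_forward(net, problem$image)
  gates <- gates_from_trace(trace)
  tg <- problem$target_index
  m <- 2^n
  vals <- numeric(m)
  for (i in seq_len(m) - 1L) {
    g <- rev(as.integer(intToBits(i))[seq_len(n)])   # gate 1 = most significant
    ofs <- 0L
    for (j in seq_along(relus)) {
      gates$relu[[relus[j]]] <- g[(ofs + 1L):(ofs + sizes[j])]
      ofs <- ofs + sizes[j]
    }
    vals[i + 1L] <- feedback_objective(net, problem$image, gates, tg)
  }
  best <- which(vals == max(vals))[1L]   # ascending i is lexicographic order
  g <- rev(as.integer(intToBits(best - 1L))[seq_len(n)])
  ofs <- 0L
  for (j in seq_along(relus)) {
    gates$relu[[relus[j]]] <- g[(ofs + 1L):(ofs + sizes[j])]
    ofs <- ofs + sizes[j]
  }
  gates$provenance <- "manual"
  list(gates = gates, objective = vals[best], n_gates = n)
}

#' @export
print.fbcnn_feedback <- function(x, ...) {
  cat(sprintf("Feedback optimization (%s): target %d\n",
              toupper(x$algorithm), x$target_index))
  cat(sprintf("  objective %.6g -> %.6g in %d sweep(s)%s\n",
              x$initial_objective, utils::tail(x$objective_trajectory, 1L),
              x$sweeps_used, if (x$converged) ", converged" else ""))
  cat("  closed gate fraction:",
      paste(sprintf("%s=%.2f", names(x$closed_fraction), x$closed_fraction),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.fbcnn_feedback <- function(x, ...) {
  traj <- c(x$initial_objective, x$objective_trajectory)
  graphics::plot(seq_along(traj) - 1L, traj, type = "s",
                 xlab = "layer-update step", ylab = "objective",
                 main = sprintf("%s objective trajectory", toupper(x$algorithm)),
                 ...)
  invisible(x)
}

#' Save / load a gate state
#'
#' @param gates An `"fbcnn_gates"` object.
#' @param path File path.
#' @export
gates_save <- function(gates, path) {
  saveRDS(gates, path)
  invisible(path)
}

#' @rdname gates_save
#' @export
gates_load <- function(path) {
  g <- readRDS(path)
  if (!inherits(g, "fbcnn_gates")) stop("file does not contain a gate state")
  g
}
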