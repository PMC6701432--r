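# Input-space saliency from converged feedback gates: the gradient of the
# target neuron through the gated network, its 0-255 visualization, and the
# L2-normalized energy map.

#' Input-space gradient map through the gated network
#'
#' Sets the gradient of the target neuron to 1 and backpropagates through the
#' frozen-switch network down to the image, yielding a gradient map with the
#' input's shape. Any gate provenance (feedforward, FR, FS, manual) is
#' accepted.
#'
#' @param net An `"fbcnn_net"` (or fitted `"fbcnn"`).
#' @param image Input image.
#' @param gates Gate state, typically the `gates` field of an
#'   `"fbcnn_feedback"` result.
#' @param target_index 1-based index of the target logit.
#' @return Object of class `"fbcnn_gradient_map"`: numeric array shaped like
#'   the input.
#' @export
gradient_map <- function(net, image, gates, target_index) {
  if (inherits(net, "fbcnn")) net <- net$net
  .check_gates(net, gates)
  X <- .as_row(net, image)
  fw <- .gated_forward_mat(net, X, gates, keep_cache = TRUE)
  ll <- .logit_layer(net)
  dout <- net$layers[[ll]]$dout
  if (target_index < 1L || target_index > dout)
    stop("target_index out of range 1..", dout)
  dOut <- matrix(0, 1L, dout)
  dOut[1L, target_index] <- 1
  g <- .gated_backward(net, fw, gates, dOut, from = ll, to = 0L)
  structure(array(as.numeric(g), dim = net$input_shape),
            class = "fbcnn_gradient_map")
}

#' Min-max visualization map
#'
#' Rescales a gradient map to the 0-255 display range with
#' `255 * (x - min) / (max - min)`, the minimum and maximum taken jointly
#' over all channels. The output is kept real-valued; quantization to 8 bits
#' happens only at PNG export.
#'
#' @param g A gradient map (array) from [gradient_map()].
#' @return Array of the same shape with minimum exactly 0 and maximum
#'   exactly 255.
#' @export
visualization_map <- function(g) {
  v <- as.numeric(g)
  lo <- min(v); hi <- max(v)
  if (hi == lo)
    stop("degenerate gradient map: constant value, min-max range is empty")
  out <- 255 * (unclass(g) - lo) / (hi - lo)
  array(out, dim = dim(g))
}

#' Energy map
#'
#' Per-pixel sum of the absolute values of the gradient map's channels,
#' normalized so the whole map has unit L2 norm. The map is non-negative and
#' invariant to rescaling of the gradient map.
#'
#' @param g A gradient map (H x W x C array; C = 1 reduces to the absolute
#'   value).
#' @return Single-channel `H x W` matrix of class `"fbcnn_energy_map"` with
#'   `sum(map^2) == 1`.
#' @export
energy_map <- function(g) {
  a <- unclass(g)
  if (is.null(dim(a))) a <- array(a, c(length(a), 1L, 1L))
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  e <- apply(abs(a), c(1L, 2L), sum)
  nrm <- sqrt(sum(e^2))
  if (nrm == 0) stop("degenerate gradient map: identically zero")
  structure(e / nrm, class = "fbcnn_energy_map")
}

#' Write a visualization map as an 8-bit grayscale PNG
#'
#' Values are quantized with round-half-even and written on the 0-255 scale.
#'
#' @param v Visualization map from [visualization_map()].
#' @param path Output file path.
#' @export
write_visualization_png <- function(v, path) {
  a <- unclass(v)
  if (length(dim(a)) == 3L && dim(a)[3L] == 1L) a <- a[, , 1L]
  png::writePNG(round(a) / 255, path)
  invisible(path)
}
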