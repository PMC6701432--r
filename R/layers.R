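# Layer specifications and per-layer forward/backward kernels.
#
# All tensors are carried as B x D matrices whose columns follow R's
# column-major flattening of an (H, W, C) array: flat index
# h + (w-1)*H + (c-1)*H*W. Convolution and pooling are implemented as
# precomputed gather indices (im2col) followed by dense matrix products,
# so the only numerical engine is BLAS.

#' Layer constructors
#'
#' Build the layer specifications accepted by [net_build()]. A network is an
#' ordered list of these; channel and dimension contracts are validated when
#' the network is built.
#'
#' @param kernel_size Side of the square convolution kernel, in pixels (>= 1).
#' @param out_channels Number of convolution kernels (output channels).
#' @param padding Either `"valid"` (no padding, output shrinks by
#'   `kernel_size - 1`) or `"same"` (zero padding, spatial size preserved).
#' @param in_channels Optional declared input channel count; validated against
#'   the chain when given.
#' @param window Pooling window side in pixels (>= 2).
#' @param stride Pooling stride in pixels; defaults to the window side
#'   (non-overlapping pooling). Trailing rows/columns that do not fill a
#'   window are dropped.
#' @param units Output dimension of the dense (fully connected) layer.
#' @param in_dim Optional declared input dimension of a dense layer; validated
#'   against the chain when given.
#'
#' @details Convolution is cross-correlation (no kernel flip): each output
#'   channel is the sum over input channels of the per-channel correlation of
#'   the input with a `kernel_size` x `kernel_size` kernel, plus a per-channel
#'   bias. The rectifier is `max(0, x)` elementwise; max pooling takes the
#'   maximum over each window and records its argmax position.
#'
#' @return A layer specification (list with class `"fbcnn_layer"`).
#' @seealso [net_build()]
#' @export
conv_layer <- function(kernel_size, out_channels, padding = c("valid", "same"),
                       in_channels = NULL) {
  padding <- match.arg(padding)
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 1L) stop("conv kernel_size must be >= 1")
  if (out_channels < 1L) stop("conv out_channels must be >= 1")
  structure(list(kind = "conv", kernel_size = kernel_size,
                 out_channels = as.integer(out_channels), padding = padding,
                 in_channels = if (!is.null(in_channels)) as.integer(in_channels)),
            class = "fbcnn_layer")
}

#' @rdname conv_layer
#' @export
relu_layer <- function() {
  structure(list(kind = "relu"), class = "fbcnn_layer")
}

#' @rdname conv_layer
#' @export
maxpool_layer <- function(window = 2L, stride = window) {
  window <- as.integer(window); stride <- as.integer(stride)
  if (window < 2L) stop("maxpool window must be >= 2")
  if (stride < 1L) stop("maxpool stride must be >= 1")
  structure(list(kind = "maxpool", window = window, stride = stride),
            class = "fbcnn_layer")
}

#' @rdname conv_layer
#' @export
flatten_layer <- function() {
  structure(list(kind = "flatten"), class = "fbcnn_layer")
}

#' @rdname conv_layer
#' @export
dense_layer <- function(units, in_dim = NULL) {
  if (units < 1L) stop("dense units must be >= 1")
  structure(list(kind = "dense", units = as.integer(units),
                 in_dim = if (!is.null(in_dim)) as.integer(in_dim)),
            class = "fbcnn_layer")
}

#' @rdname conv_layer
#' @export
softmax_layer <- function() {
  structure(list(kind = "softmax"), class = "fbcnn_layer")
}

# Gather indices for convolution: idx[p + (q-1)*P] is the flat input pixel
# feeding output position p through kernel element q; out-of-image positions
# (same padding) point at the extra zero column din+1.
.conv_indices <- function(H, W, C, K, padding) {
  if (padding == "valid") {
    Ho <- H - K + 1L; Wo <- W - K + 1L
    if (Ho < 1L || Wo < 1L)
      stop(sprintf("conv kernel %d does not fit input %dx%d (valid padding)", K, H, W))
    pad <- 0L
  } else {
    Ho <- H; Wo <- W
    pad <- (K - 1L) %/% 2L
  }
  P <- Ho * Wo; Q <- K * K * C
  ho <- rep(seq_len(Ho), Wo); wo <- rep(seq_len(Wo), each = Ho)
  kh <- rep(seq_len(K), K * C)
  kw <- rep(rep(seq_len(K), each = K), C)
  cc <- rep(seq_len(C), each = K * K)
  row <- outer(ho, kh, `+`) - 1L - pad
  col <- outer(wo, kw, `+`) - 1L - pad
  cm  <- matrix(cc, P, Q, byrow = TRUE)
  pix <- row + (col - 1L) * H + (cm - 1L) * (H * W)
  out <- row < 1L | row > H | col < 1L | col > W
  pix[out] <- H * W * C + 1L
  list(idx = as.integer(pix), Ho = Ho, Wo = Wo, P = P, Q = Q,
       padded = any(out))
}

# Gather indices for max pooling; p runs over (ho, wo, c) column-major and
# q over the s*s window elements.
.pool_indices <- function(H, W, C, s, stride) {
  Ho <- (H - s) %/% stride + 1L
  Wo <- (W - s) %/% stride + 1L
  if (Ho < 1L || Wo < 1L)
    stop(sprintf("maxpool window %d does not fit input %dx%d", s, H, W))
  P <- Ho * Wo * C; W2 <- s * s
  ho <- rep(seq_len(Ho), Wo * C)
  wo <- rep(rep(seq_len(Wo), each = Ho), C)
  cc <- rep(seq_len(C), each = Ho * Wo)
  u <- rep(seq_len(s), s); v <- rep(seq_len(s), each = s)
  row <- outer((ho - 1L) * stride + 1L, u - 1L, `+`)
  col <- outer((wo - 1L) * stride + 1L, v - 1L, `+`)
  cm <- matrix(cc, P, W2, byrow = FALSE)
  pix <- row + (col - 1L) * H + (cm - 1L) * (H * W)
  list(idx = as.integer(pix), Ho = Ho, Wo = Wo, P = P, W2 = W2)
}

.add_bias <- function(Y, b) Y + rep(b, each = nrow(Y))

# Forward one layer on a B x din matrix. `gate` supplies feedback-gate
# semantics: relu becomes pure pass-through of the pre-activation where z = 1
# (zero elsewhere), maxpool reads its recorded switch position instead of
# recomputing the argmax. Returns list(Y, cache).
.layer_forward <- function(layer, par, X, gate = NULL, keep_cache = TRUE) {
  B <- nrow(X)
  switch(layer$kind,
    conv = {
      Xp <- if (layer$ix$padded) cbind(X, 0) else X
      Z <- Xp[, layer$ix$idx, drop = FALSE]
      dim(Z) <- c(B * layer$ix$P, layer$ix$Q)
      Y <- .add_bias(Z %*% par$W, par$b)
      dim(Y) <- c(B, layer$dout)
      list(Y = Y, cache = if (keep_cache) list(Z = Z))
    },
    relu = {
      if (is.null(gate)) {
        mask <- X > 0
        list(Y = X * mask, cache = if (keep_cache) list(mask = mask))
      } else {
        z <- rep(gate, each = B)
        list(Y = X * z, cache = if (keep_cache) list(z = gate))
      }
    },
    maxpool = {
      Z <- X[, layer$ix$idx, drop = FALSE]
      dim(Z) <- c(B * layer$ix$P, layer$ix$W2)
      if (is.null(gate)) {
        arg <- max.col(Z, ties.method = "first")
      } else {
        if (B != 1L) stop("switch-frozen pooling supports single images only")
        arg <- gate
      }
      Y <- Z[cbind(seq_len(B * layer$ix$P), arg)]
      dim(Y) <- c(B, layer$dout)
      list(Y = Y, cache = if (keep_cache) list(arg = arg))
    },
    flatten = list(Y = X, cache = NULL),
    dense = {
      Y <- .add_bias(X %*% par$W, par$b)
      list(Y = Y, cache = if (keep_cache) list(X = X))
    },
    softmax = {
      E <- exp(X - apply(X, 1L, max))
      Y <- E / rowSums(E)
      list(Y = Y, cache = if (keep_cache) list(Y = Y))
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

# Backward one layer: given dY (B x dout) return dX and parameter gradients.
# `gate` replaces the stored rectifier pattern for gated networks.
.layer_backward <- function(layer, par, cache, dY, gate = NULL) {
  B <- nrow(dY)
  switch(layer$kind,
    conv = {
      P <- layer$ix$P; Q <- layer$ix$Q
      dY2 <- dY; dim(dY2) <- c(B * P, layer$out_dims[3L])
      dW <- crossprod(cache$Z, dY2)
      db <- colSums(dY2)
      dM <- tcrossprod(dY2, par$W)
      dim(dM) <- c(B, P * Q)
      din <- layer$din
      dX <- matrix(0, B, din)
      idx <- layer$ix$idx
      for (q in seq_len(Q)) {
        cols <- ((q - 1L) * P + 1L):(q * P)
        tgt <- idx[cols]
        sel <- tgt <= din
        if (all(sel)) {
          dX[, tgt] <- dX[, tgt, drop = FALSE] + dM[, cols, drop = FALSE]
        } else if (any(sel)) {
          dX[, tgt[sel]] <- dX[, tgt[sel], drop = FALSE] + dM[, cols[sel], drop = FALSE]
        }
      }
      list(dX = dX, dW = dW, db = db)
    },
    relu = {
      if (is.null(gate)) list(dX = dY * cache$mask)
      else list(dX = dY * rep(gate, each = B))
    },
    maxpool = {
      P <- layer$ix$P
      arg <- if (is.null(gate)) cache$arg else gate
      r <- seq_len(B * P)
      p <- ((r - 1L) %/% B) + 1L
      b <- ((r - 1L) %% B) + 1L
      pix <- layer$ix$idx[p + (arg - 1L) * P]
      dX <- matrix(0, B, layer$din)
      dX[b + (pix - 1L) * B] <- as.vector(dY)
      list(dX = dX)
    },
    flatten = list(dX = dY),
    dense = list(dX = tcrossprod(dY, par$W),
                 dW = crossprod(cache$X, dY),
                 db = colSums(dY)),
    softmax = {
      Y <- cache$Y
      list(dX = Y * (dY - rowSums(dY * Y)))
    },
    stop("unknown layer kind: ", layer$kind)
  )
}
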