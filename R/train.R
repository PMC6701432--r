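#' Training control parameters
#'
#' @param learning_rate SGD step size (> 0).
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of passes over the data (>= 1).
#' @param seed Integer seed driving parameter initialization and shuffling
#'   (mandatory for reproducible runs).
#' @param init_scale Multiplier on the fan-in-scaled uniform initialization.
#' @param l2 Optional L2 penalty coefficient on weights.
#' @return A list of class `"fbcnn_control"`.
#' @export
train_control <- function(learning_rate = 0.1, batch_size = 32L, epochs = 8L,
                          seed = 1L, init_scale = 1, l2 = 0) {
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (is.null(seed)) stop("seed is mandatory")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 init_scale = init_scale, l2 = l2),
            class = "fbcnn_control")
}

# Coerce patches (n x din matrix, or (n,H,W[,C]) array) to the batch matrix
# layout: row i is the column-major (H,W,C) flattening of sample i.
.as_batch <- function(net, x) {
  if (is.matrix(x)) X <- x
  else if (is.array(x)) {
    d <- dim(x)
    X <- matrix(x, d[1L], prod(d[-1L]))
  } else stop("patches must be a matrix or array with samples in the first dimension")
  if (ncol(X) != prod(net$input_shape))
    stop("patches have ", ncol(X), " values per sample; model expects ",
         prod(net$input_shape))
  X
}

#' Supervised training by mini-batch SGD
#'
#' Trains a softmax-headed network on labeled patches with cross-entropy loss
#' and plain mini-batch stochastic gradient descent. Shuffling is seeded, so
#' runs are reproducible.
#'
#' @param net An `"fbcnn_net"` whose last layer is a softmax.
#' @param x Patches: `n x d` matrix or `(n, H, W[, C])` array.
#' @param y Integer class labels in `0 .. n_classes - 1`.
#' @param control A [train_control()] list.
#' @return List with `net` (trained network) and `loss` (mean training
#'   cross-entropy per epoch).
#' @export
net_train <- function(net, x, y, control = train_control()) {
  n <- nrow(if (is.matrix(x)) x else x)
  X <- .as_batch(net, x)
  n <- nrow(X)
  if (n == 0L) stop("empty training dataset")
  if (length(y) != n) stop("length(y) != number of patches")
  nl <- length(net$layers)
  if (net$layers[[nl]]$kind != "softmax")
    stop("supervised training requires a softmax head")
  k <- net$layers[[nl]]$dout
  y <- as.integer(y)
  if (any(y < 0L | y >= k)) stop("labels must lie in 0..", k - 1L)
  lr <- control$learning_rate; l2 <- control$l2
  losses <- numeric(control$epochs)
  net <- .with_seed(.derive_seed(control$seed, 1L), {
    for (ep in seq_len(control$epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = control$batch_size)) {
        rows <- ord[start:min(start + control$batch_size - 1L, n)]
        B <- length(rows)
        fw <- .net_forward_mat(net, X[rows, , drop = FALSE], keep_cache = TRUE)
        p <- fw$out
        li <- cbind(seq_len(B), y[rows] + 1L)
        loss <- -mean(log(p[li]))
        if (!is.finite(loss))
          stop("non-finite training loss in epoch ", ep)
        tot <- tot + loss * B
        dLogit <- p
        dLogit[li] <- dLogit[li] - 1
        dLogit <- dLogit / B
        bk <- .net_backward_mat(net, fw, dLogit, from = nl - 1L)
        for (j in seq_along(net$params)) {
          if (is.null(bk$grads[[j]])) next
          net$params[[j]]$W <- net$params[[j]]$W -
            lr * (bk$grads[[j]]$dW + l2 * net$params[[j]]$W)
          net$params[[j]]$b <- net$params[[j]]$b - lr * bk$grads[[j]]$db
        }
      }
      losses[ep] <- tot / n
    }
    net
  })
  list(net = net, loss = losses)
}

#' Greedy layer-wise denoising pretraining
#'
#' Initializes the feature-extracting layers one block at a time. Each
#' trainable block (a convolution or hidden dense layer together with its
#' following rectifier) is trained as a denoising reconstructor: its input is
#' corrupted with additive Gaussian noise, passed through the block and a
#' temporary linear decoder, and the mean squared error against the clean,
#' uncorrupted input is minimized. Earlier blocks are frozen while later ones
#' train (each block sees the hidden output of its predecessors), and the
#' decoders are discarded. The classification head (last dense layer) is left
#' at its initialization for supervised fine-tuning.
#'
#' @param net An `"fbcnn_net"`.
#' @param x Unlabeled patches (matrix or array as in [net_train()]).
#' @param noise_sigma Standard deviation of the additive corruption (>= 0).
#' @param control A [train_control()] list.
#' @return The network with pretrained feature layers.
#' @export
net_pretrain <- function(net, x, noise_sigma, control = train_control()) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  X <- .as_batch(net, x)
  n <- nrow(X)
  if (n == 0L) stop("empty pretraining dataset")
  kinds <- vapply(net$layers, `[[`, "", "kind")
  trainable <- which(kinds %in% c("conv", "dense"))
  if (length(trainable) == 0L) stop("model has no trainable encoder block")
  blocks <- setdiff(trainable, max(trainable))   # keep the head for fine-tuning
  lr <- control$learning_rate
  loss_hist <- list()
  net <- .with_seed(.derive_seed(control$seed, 2L), {
    for (li in blocks) {
      # clean inputs to this block under the (frozen) earlier layers
      U <- X
      if (li > 1L) {
        for (j in seq_len(li - 1L))
          U <- .layer_forward(net$layers[[j]], net$params[[j]], U,
                              keep_cache = FALSE)$Y
      }
      has_relu <- li < length(net$layers) && kinds[li + 1L] == "relu"
      dh <- net$layers[[li]]$dout
      din <- ncol(U)
      a <- 1 / sqrt(dh)
      Wd <- matrix(stats::runif(dh * din, -a, a), dh, din)
      bd <- numeric(din)
      ep_loss <- numeric(control$epochs)
      for (ep in seq_len(control$epochs)) {
        ord <- sample.int(n)
        tot <- 0
        for (start in seq(1L, n, by = control$batch_size)) {
          rows <- ord[start:min(start + control$batch_size - 1L, n)]
          B <- length(rows)
          Uc <- U[rows, , drop = FALSE]
          V <- Uc + if (noise_sigma > 0)
            matrix(stats::rnorm(B * din, 0, noise_sigma), B, din) else 0
          st1 <- .layer_forward(net$layers[[li]], net$params[[li]], V)
          H <- st1$Y
          st2 <- if (has_relu)
            .layer_forward(net$layers[[li + 1L]], NULL, H) else NULL
          Hr <- if (has_relu) st2$Y else H
          R <- .add_bias(Hr %*% Wd, bd)
          tot <- tot + mean((R - Uc)^2) * B
          dR <- 2 * (R - Uc) / (B * din)
          dWd <- crossprod(Hr, dR); dbd <- colSums(dR)
          dH <- tcrossprod(dR, Wd)
          if (has_relu)
            dH <- .layer_backward(net$layers[[li + 1L]], NULL, st2$cache, dH)$dX
          bk <- .layer_backward(net$layers[[li]], net$params[[li]], st1$cache, dH)
          net$params[[li]]$W <- net$params[[li]]$W - lr * bk$dW
          net$params[[li]]$b <- net$params[[li]]$b - lr * bk$db
          Wd <- Wd - lr * dWd; bd <- bd - lr * dbd
        }
        ep_loss[ep] <- tot / n
      }
      loss_hist[[paste0("layer", li)]] <- ep_loss
    }
    net
  })
  attr(net, "pretrain_loss") <- loss_hist
  net
}

#' Default patch-classifier architecture
#'
#' The stock stack used throughout the package for 25x25 grayscale patches:
#' two convolution + rectifier + pooling stages, a hidden dense layer, and a
#' softmax classification head. It is the smallest stack with two
#' convolutional feedback (ReLU) layers at desk scale.
#'
#' @param input_shape `c(H, W, C)` of one patch; default `c(25, 25, 1)`.
#' @param n_classes Number of output classes.
#' @param hidden Hidden dense width.
#' @return List of layer specifications for [net_build()].
#' @export
default_architecture <- function(input_shape = c(25L, 25L, 1L), n_classes = 2L,
                                 hidden = 64L) {
  list(conv_layer(5L, 8L), relu_layer(), maxpool_layer(2L),
       conv_layer(5L, 16L), relu_layer(), maxpool_layer(2L),
       flatten_layer(), dense_layer(hidden), relu_layer(),
       dense_layer(n_classes), softmax_layer())
}

#' Fit a patch classifier
#'
#' The package's central fitting function: builds (or accepts) a
#' softmax-headed convolutional network, optionally pretrains its feature
#' layers as denoising reconstructors, and fine-tunes the whole network with
#' supervised mini-batch SGD on labeled patches. All randomness flows through
#' `control$seed`.
#'
#' @param x Labeled patches: `n x d` matrix or `(n, H, W[, C])` array with
#'   values in `[0, 1]`.
#' @param y Integer labels in `0 .. n_classes - 1` (class of each patch's
#'   center pixel in the segmentation pipeline).
#' @param layers Optional architecture (list of layer specs); defaults to
#'   [default_architecture()] for the observed patch shape.
#' @param input_shape Patch shape `c(H, W, C)`; inferred from `x` when it is
#'   an array.
#' @param control A [train_control()] list.
#' @param pretrain Logical; run [net_pretrain()] before fine-tuning.
#' @param noise_sigma Corruption level for pretraining.
#' @param pretrain_control Control for the pretraining stage; defaults to
#'   `control` with 2 epochs.
#' @return Object of class `"fbcnn"`: fields `net`, `loss` (per-epoch
#'   training cross-entropy), `classes`, `patch_shape`, `control`, `call`.
#' @export
fbcnn_fit <- function(x, y, layers = NULL, input_shape = NULL,
                      control = train_control(), pretrain = FALSE,
                      noise_sigma = 0.1, pretrain_control = NULL) {
  cl <- match.call()
  if (is.null(input_shape)) {
    if (is.array(x) && !is.matrix(x)) {
      d <- dim(x)[-1L]
      input_shape <- if (length(d) == 2L) c(d, 1L) else d
    } else stop("input_shape must be given when x is a plain matrix")
  }
  y <- as.integer(y)
  classes <- sort(unique(y))
  n_classes <- max(classes) + 1L
  if (is.null(layers))
    layers <- default_architecture(input_shape, n_classes = n_classes)
  net <- net_build(layers, input_shape, seed = .derive_seed(control$seed, 0L),
                   init_scale = control$init_scale)
  if (pretrain) {
    if (is.null(pretrain_control)) {
      pretrain_control <- control
      pretrain_control$epochs <- 2L
    }
    net <- net_pretrain(net, x, noise_sigma = noise_sigma,
                        control = pretrain_control)
  }
  tr <- net_train(net, x, y, control = control)
  structure(list(net = tr$net, loss = tr$loss, classes = seq_len(n_classes) - 1L,
                 patch_shape = as.integer(input_shape), control = control,
                 pretrained = isTRUE(pretrain), call = cl),
            class = "fbcnn")
}

#' @export
print.fbcnn <- function(x, ...) {
  cat("Patch classifier (feedback-gated CNN)\n")
  cat("  patch shape:", paste(x$patch_shape, collapse = "x"),
      " classes:", length(x$classes), "\n")
  cat("  training loss:", sprintf("%.4f", x$loss[1L]), "->",
      sprintf("%.4f", x$loss[length(x$loss)]),
      sprintf("(%d epochs)\n", length(x$loss)))
  invisible(x)
}

#' @export
summary.fbcnn <- function(object, ...) {
  print(object)
  print(object$net)
  invisible(object)
}

#' @export
coef.fbcnn <- function(object, ...) object$net$params

#' Predict classes or probabilities for patches
#'
#' @param object A fitted `"fbcnn"`.
#' @param newdata Patches (matrix or array as in [fbcnn_fit()]).
#' @param type `"class"` for hard labels (0-based), `"prob"` for the softmax
#'   probability matrix.
#' @param batch Internal processing chunk size.
#' @param ... Unused.
#' @export
predict.fbcnn <- function(object, newdata, type = c("class", "prob"),
                          batch = 512L, ...) {
  type <- match.arg(type)
  X <- .as_batch(object$net, newdata)
  n <- nrow(X)
  k <- object$net$layers[[length(object$net$layers)]]$dout
  P <- matrix(NA_real_, n, k)
  for (start in seq(1L, n, by = batch)) {
    rows <- start:min(start + batch - 1L, n)
    P[rows, ] <- .net_forward_mat(object$net, X[rows, , drop = FALSE])$out
  }
  if (type == "prob") P else max.col(P, ties.method = "first") - 1L
}

#' @export
plot.fbcnn <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "b", xlab = "epoch",
                 ylab = "training cross-entropy", main = "fbcnn training", ...)
  invisible(x)
}
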