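# Patch-based segmentation pipeline: dense per-pixel classification by the
# patch classifier, intensity-band threshold refinement, and morphological
# opening/closing, with Dice/IoU/accuracy evaluation.

#' Segmentation configuration
#'
#' @param patch_size Odd patch side in pixels (>= 3); must match the fitted
#'   classifier's patch shape.
#' @param stride Spacing of classified patch centers; pixels between centers
#'   are filled by nearest-center assignment.
#' @param threshold_k Width of the kept intensity band around the foreground
#'   mean, in standard deviations (> 0).
#' @param morph_radius Radius of the square structuring element (side
#'   `2 * morph_radius + 1`), in pixels (>= 1).
#' @param morph_order `"open_close"` (opening then closing, the default) or
#'   `"close_open"`.
#' @param class_of_interest Label treated as foreground.
#' @return A list of class `"fbcnn_seg_config"`.
#' @export
seg_config <- function(patch_size = 25L, stride = 1L, threshold_k = 2,
                       morph_radius = 1L,
                       morph_order = c("open_close", "close_open"),
                       class_of_interest = 1L) {
  morph_order <- match.arg(morph_order)
  patch_size <- as.integer(patch_size)
  if (patch_size < 3L || patch_size %% 2L == 0L)
    stop("patch_size must be odd and >= 3")
  if (stride < 1L) stop("stride must be >= 1")
  if (threshold_k <= 0) stop("threshold_k must be > 0")
  if (morph_radius < 1L) stop("morph_radius must be >= 1")
  structure(list(patch_size = patch_size, stride = as.integer(stride),
                 threshold_k = threshold_k, morph_radius = as.integer(morph_radius),
                 morph_order = morph_order,
                 class_of_interest = as.integer(class_of_interest)),
            class = "fbcnn_seg_config")
}

#' Min-max intensity normalization
#'
#' Maps an image onto `[0, 1]` by `(f - min) / (max - min)`.
#'
#' @param image Numeric matrix or array.
#' @return Image of the same shape with minimum 0 and maximum 1.
#' @export
normalize_image <- function(image) {
  lo <- min(image); hi <- max(image)
  if (hi == lo) stop("degenerate image: constant intensity, cannot normalize")
  (image - lo) / (hi - lo)
}

# Symmetric (mirror about the border) index into 1..n.
.reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 1L - i, i)
  i <- ifelse(i > n, 2L * n + 1L - i, i)
  if (any(i < 1L | i > n)) stop("patch larger than twice the image; cannot reflect-pad")
  i
}

#' Extract centered patches with reflect padding
#'
#' One `patch_size` x `patch_size` patch per stride-spaced pixel; borders are
#' handled by mirror (symmetric) padding so every pixel can serve as a patch
#' center. When a label mask is given, each patch is labeled with the mask
#' value at its center.
#'
#' @param image Normalized `H x W` matrix.
#' @param patch_size Odd patch side.
#' @param stride Center spacing in pixels.
#' @param labels Optional integer mask of the same shape as `image`.
#' @return List with `x` (`n x patch_size^2` matrix, rows in the package's
#'   column-major patch layout), `centers` (`n x 2` matrix of row/col
#'   indices), and `y` (labels at centers, or `NULL`).
#' @export
extract_patches <- function(image, patch_size = 25L, stride = 1L, labels = NULL) {
  if (patch_size %% 2L == 0L) stop("patch_size must be odd")
  stopifnot(is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  m <- (patch_size - 1L) %/% 2L
  rows <- seq(1L, H, by = stride)
  cols <- seq(1L, W, by = stride)
  centers <- cbind(row = rep(rows, times = length(cols)),
                   col = rep(cols, each = length(rows)))
  n <- nrow(centers)
  off <- -m:m
  # patch pixel (u, v) for center (r, c) reads image[reflect(r+u), reflect(c+v)]
  ridx <- outer(centers[, 1L], off, `+`)          # n x patch_size
  cidx <- outer(centers[, 2L], off, `+`)
  ridx[] <- .reflect_index(as.integer(ridx), H)
  cidx[] <- .reflect_index(as.integer(cidx), W)
  p <- patch_size
  # build flat indices: for each center, column-major over (u, v)
  X <- matrix(NA_real_, n, p * p)
  for (v in seq_len(p)) {
    cc <- cidx[, v]
    for (u in seq_len(p)) {
      X[, u + (v - 1L) * p] <- image[ridx[, u] + (cc - 1L) * H]
    }
  }
  y <- if (!is.null(labels)) as.integer(labels[centers]) else NULL
  list(x = X, centers = centers, y = y)
}

#' Dense per-pixel prediction
#'
#' Classifies a patch centered at every stride-spaced pixel and maps the
#' predicted class of each patch back to its center pixel; with `stride > 1`
#' the remaining pixels take the class of their nearest center. The initial
#' mask is the set of pixels predicted as the class of interest.
#'
#' @param fit A fitted `"fbcnn"` classifier.
#' @param image Normalized `H x W` matrix.
#' @param config A [seg_config()].
#' @return Binary `H x W` initial mask (0/1 matrix).
#' @export
dense_predict <- function(fit, image, config = seg_config()) {
  stopifnot(inherits(fit, "fbcnn"))
  if (config$patch_size != fit$patch_shape[1L] ||
      config$patch_size != fit$patch_shape[2L])
    stop("config patch_size ", config$patch_size,
         " does not match the classifier's patch shape ",
         paste(fit$patch_shape, collapse = "x"))
  H <- nrow(image); W <- ncol(image)
  pa <- extract_patches(image, config$patch_size, config$stride)
  cls <- predict(fit, pa$x, type = "class")
  rows <- seq(1L, H, by = config$stride)
  cols <- seq(1L, W, by = config$stride)
  cg <- matrix(cls, length(rows), length(cols))
  if (config$stride == 1L) {
    cm <- cg
  } else {
    # nearest-center fill
    ri <- pmin(round((seq_len(H) - 1L) / config$stride) + 1L, length(rows))
    ci <- pmin(round((seq_len(W) - 1L) / config$stride) + 1L, length(cols))
    cm <- cg[ri, ci, drop = FALSE]
  }
  (cm == config$class_of_interest) + 0L
}

#' Intensity-band threshold refinement
#'
#' Estimates the mean and standard deviation of the image intensities inside
#' the initial mask and removes mask pixels whose intensity falls outside the
#' closed band `[mu - k * sigma, mu + k * sigma]`. Pixels are only ever
#' removed, never added.
#'
#' @param image Normalized `H x W` matrix (the pipeline thresholds the
#'   normalized intensities).
#' @param mask Binary initial mask.
#' @param config A [seg_config()] supplying `threshold_k`.
#' @return Refined binary mask, a subset of `mask`.
#' @export
threshold_refine <- function(image, mask, config = seg_config()) {
  stopifnot(all(dim(image) == dim(mask)))
  sel <- mask == 1L
  if (!any(sel)) {
    warning("empty initial mask; threshold refinement returns an empty mask")
    return(mask * 0L)
  }
  v <- image[sel]
  mu <- mean(v)
  sg <- stats::sd(v)
  if (is.na(sg)) sg <- 0   # single-pixel mask
  k <- config$threshold_k
  keep <- sel & image >= mu - k * sg & image <= mu + k * sg
  keep + 0L
}

#' Morphological mask refinement
#'
#' Opening (erosion then dilation) removes isolated specks and thin
#' protrusions; closing (dilation then erosion) fills small gaps and
#' concavities. Both use a square structuring element of side
#' `2 * morph_radius + 1`, applied in the configured order.
#'
#' @param mask Binary `H x W` matrix (values 0/1).
#' @param config A [seg_config()] supplying `morph_radius` and `morph_order`.
#' @return Refined binary mask.
#' @export
morphological_refine <- function(mask, config = seg_config()) {
  if (!all(mask %in% c(0L, 1L)))
    stop("morphological refinement expects a binary 0/1 mask")
  kern <- EBImage::makeBrush(2L * config$morph_radius + 1L, shape = "box")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  m <- if (config$morph_order == "open_close") {
    EBImage::closing(EBImage::opening(m, kern), kern)
  } else {
    EBImage::opening(EBImage::closing(m, kern), kern)
  }
  matrix(as.integer(m > 0.5), nrow(mask), ncol(mask))
}

#' Overlap metrics between binary masks
#'
#' Dice ratio `2|A∩B| / (|A| + |B|)`, intersection-over-union
#' `|A∩B| / |A∪B|`, and per-pixel accuracy. Two empty masks count as a
#' perfect match (Dice and IoU 1).
#'
#' @param pred,truth Binary masks of identical shape.
#' @return Named numeric vector `c(dice, iou, accuracy)`.
#' @export
evaluate_masks <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  a <- pred == 1L; b <- truth == 1L
  inter <- sum(a & b)
  sa <- sum(a); sb <- sum(b)
  dice <- if (sa + sb == 0L) 1 else 2 * inter / (sa + sb)
  uni <- sa + sb - inter
  iou <- if (uni == 0L) 1 else inter / uni
  acc <- mean(a == b)
  c(dice = dice, iou = iou, accuracy = acc)
}

#' Segment an image end to end
#'
#' The full pipeline: min-max normalization, dense patch classification to an
#' initial mask, intensity-band threshold refinement, and morphological
#' opening/closing. All three masks are retained for inspection; when a
#' ground-truth mask is supplied, Dice/IoU/accuracy are computed for each
#' stage.
#'
#' @param fit A fitted `"fbcnn"` classifier.
#' @param image Raw grayscale `H x W` matrix (any intensity range).
#' @param config A [seg_config()].
#' @param truth Optional binary ground-truth mask.
#' @return Object of class `"fbcnn_segmentation"`: `initial_mask`,
#'   `threshold_mask`, `final_mask`, `metrics` (per-stage matrix or `NULL`),
#'   `config`.
#' @export
segment_image <- function(fit, image, config = seg_config(), truth = NULL) {
  img <- normalize_image(image)
  initial <- dense_predict(fit, img, config)
  thresh <- threshold_refine(img, initial, config)
  final <- morphological_refine(thresh, config)
  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- rbind(initial = evaluate_masks(initial, truth),
                     threshold = evaluate_masks(thresh, truth),
                     final = evaluate_masks(final, truth))
  }
  structure(list(initial_mask = initial, threshold_mask = thresh,
                 final_mask = final, metrics = metrics, config = config),
            class = "fbcnn_segmentation")
}

#' @export
print.fbcnn_segmentation <- function(x, ...) {
  cat("Patch-based segmentation:",
      sum(x$initial_mask), "->", sum(x$threshold_mask), "->",
      sum(x$final_mask), "foreground pixels (initial -> threshold -> final)\n")
  if (!is.null(x$metrics)) {
    cat("  metrics vs ground truth:\n")
    print(round(x$metrics, 4))
  }
  invisible(x)
}

#' @export
plot.fbcnn_segmentation <- function(x, ...) {
  op <- graphics::par(mfrow = c(1L, 3L), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (nm in c("initial_mask", "threshold_mask", "final_mask")) {
    graphics::image(t(x[[nm]])[, nrow(x[[nm]]):1], axes = FALSE, main = nm,
                    col = c("black", "white"))
  }
  invisible(x)
}
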