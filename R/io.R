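# PNG input/output for grayscale images and binary masks.

#' Read and write grayscale images and masks as PNG
#'
#' Images are stored on the PNG `[0, 1]` gray scale (multi-channel files are
#' averaged to one channel on read). Masks are written with foreground 255
#' and background 0, and read back with the documented `255 -> 1` mapping
#' (any value above one half counts as foreground).
#'
#' @param path File path.
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param mask Binary 0/1 matrix.
#' @return The read functions return a matrix; the write functions return
#'   `path` invisibly.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3L])),
                                         drop = FALSE], c(1L, 2L), mean)
  a
}

#' @rdname read_image_png
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname read_image_png
#' @export
read_mask_png <- function(path) {
  a <- read_image_png(path)
  (a > 0.5) + 0L
}

#' @rdname read_image_png
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask == 1L), nrow(mask), ncol(mask)), path)
  invisible(path)
}
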