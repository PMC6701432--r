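# Synthetic lesion scenes: bright elliptical lesions on a darker background
# with a smooth low-frequency intensity inhomogeneity field and additive
# Gaussian noise, plus pixel-accurate ground-truth masks. These stand in for
# clinical slices so the whole pipeline can be exercised and scored at desk
# scale with known truth.

#' Scene generator configuration
#'
#' Defaults describe the package's canonical study conditions: 0.75 vs 0.35
#' foreground/background contrast, noise standard deviation 0.08 and
#' inhomogeneity amplitude 0.1 on the `[0, 1]` intensity scale -- separable,
#' but not trivially so, for the default 25x25 patch classifier.
#'
#' @param image_size Side of the square image in pixels.
#' @param n_lesions Integer range `c(min, max)` of lesion counts.
#' @param lesion_radius Range `c(min, max)` of ellipse semi-axes in pixels.
#' @param foreground_mean,background_mean Mean intensities on `[0, 1]`; they
#'   must differ.
#' @param noise_sigma Additive Gaussian noise standard deviation (>= 0).
#' @param inhomogeneity_amplitude Amplitude of the smooth bias field.
#' @param seed Integer seed (mandatory); all randomness flows through it.
#' @return A list of class `"fbcnn_scene_config"`.
#' @export
scene_config <- function(image_size = 64L, n_lesions = c(1L, 3L),
                         lesion_radius = c(4, 9), foreground_mean = 0.75,
                         background_mean = 0.35, noise_sigma = 0.08,
                         inhomogeneity_amplitude = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(n_lesions) == 1L) n_lesions <- c(n_lesions, n_lesions)
  if (length(lesion_radius) == 1L) lesion_radius <- rep(lesion_radius, 2L)
  if (foreground_mean < 0 || foreground_mean > 1 ||
      background_mean < 0 || background_mean > 1)
    stop("means must lie in [0, 1]")
  if (foreground_mean == background_mean)
    stop("foreground_mean must differ from background_mean")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 n_lesions = as.integer(n_lesions),
                 lesion_radius = as.numeric(lesion_radius),
                 foreground_mean = foreground_mean,
                 background_mean = background_mean,
                 noise_sigma = noise_sigma,
                 inhomogeneity_amplitude = inhomogeneity_amplitude,
                 seed = as.integer(seed)),
            class = "fbcnn_scene_config")
}

# Rasterize an axis-aligned ellipse: pixels with
# ((r - r0)/a)^2 + ((c - c0)/b)^2 <= 1.
.ellipse_mask <- function(n, r0, c0, a, b) {
  r <- matrix(seq_len(n), n, n)
  c <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((r - r0) / a)^2 + ((c - c0) / b)^2 <= 1
}

# Smooth bias field: sum of 2-3 low-frequency cosine components with seeded
# frequencies and phases, scaled to peak amplitude 1.
.bias_field <- function(n, k) {
  r <- matrix(seq_len(n), n, n) / n
  c <- matrix(seq_len(n), n, n, byrow = TRUE) / n
  f <- matrix(0, n, n)
  for (i in seq_len(k)) {
    fr <- sample(1:2, 1L); fc <- sample(1:2, 1L)
    ph <- stats::runif(2L, 0, 2 * pi)
    f <- f + cos(2 * pi * fr * r + ph[1L]) * cos(2 * pi * fc * c + ph[2L])
  }
  f / max(abs(f))
}

#' Generate one labeled lesion scene
#'
#' Draws non-overlapping axis-aligned ellipses (bounded rejection sampling),
#' composes `background + contrast * mask + amplitude * bias field +
#' Gaussian noise`, and clips to `[0, 1]`. The mask is exactly the union of
#' the rasterized ellipse supports. The same seed gives bit-identical
#' output.
#'
#' @param config A [scene_config()].
#' @return Object of class `"fbcnn_scene"`: `image` (`H x W` matrix on
#'   `[0, 1]`), `mask` (binary matrix), `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "fbcnn_scene_config"))
  n <- config$image_size
  .with_seed(config$seed, {
    k <- if (config$n_lesions[1L] == config$n_lesions[2L]) config$n_lesions[1L]
         else sample(config$n_lesions[1L]:config$n_lesions[2L], 1L)
    mask <- matrix(FALSE, n, n)
    placed <- 0L
    tries <- 0L
    while (placed < k) {
      tries <- tries + 1L
      if (tries > 100L * max(k, 1L))
        stop("could not place ", k, " non-overlapping lesions in a ",
             n, "x", n, " image after ", tries, " attempts")
      a <- stats::runif(1L, config$lesion_radius[1L], config$lesion_radius[2L])
      b <- stats::runif(1L, config$lesion_radius[1L], config$lesion_radius[2L])
      r0 <- stats::runif(1L, a + 1, n - a)
      c0 <- stats::runif(1L, b + 1, n - b)
      cand <- .ellipse_mask(n, r0, c0, a, b)
      if (any(cand & mask)) next
      mask <- mask | cand
      placed <- placed + 1L
    }
    img <- config$background_mean +
      (config$foreground_mean - config$background_mean) * mask
    if (config$inhomogeneity_amplitude != 0)
      img <- img + config$inhomogeneity_amplitude * .bias_field(n, sample(2:3, 1L))
    if (config$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(n * n, 0, config$noise_sigma), n, n)
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = mask + 0L, config = config),
              class = "fbcnn_scene")
  })
}

#' Build a class-balanced patch dataset from labeled scenes
#'
#' Samples an equal number of patch centers per class, without replacement
#' within a class, from the pooled pixels of all scenes; labels come from the
#' ground-truth masks at the patch centers. Sampling is deterministic under
#' the seed.
#'
#' @param scenes List of `"fbcnn_scene"` objects.
#' @param n_per_class Number of patches per class.
#' @param patch_size Odd patch side in pixels.
#' @param seed Integer seed.
#' @return List with `x` (`n x patch_size^2` matrix), `y` (0/1 labels), and
#'   `provenance` (sampled scene/center indices).
#' @export
make_patch_dataset <- function(scenes, n_per_class, patch_size = 25L, seed = 1L) {
  stopifnot(length(scenes) >= 1L)
  pools <- list(`0` = NULL, `1` = NULL)
  for (s in seq_along(scenes)) {
    m <- scenes[[s]]$mask
    w1 <- which(m == 1L); w0 <- which(m == 0L)
    if (length(w0)) pools[["0"]] <- rbind(pools[["0"]], cbind(s, w0))
    if (length(w1)) pools[["1"]] <- rbind(pools[["1"]], cbind(s, w1))
  }
  for (cl in c("0", "1")) {
    have <- if (is.null(pools[[cl]])) 0L else nrow(pools[[cl]])
    if (have < n_per_class)
      stop("insufficient pixels of class ", cl, ": need ", n_per_class,
           ", have ", have)
  }
  .with_seed(seed, {
    x <- NULL; y <- NULL; prov <- NULL
    for (cl in c("0", "1")) {
      pick <- pools[[cl]][sample.int(nrow(pools[[cl]]), n_per_class), , drop = FALSE]
      prov <- rbind(prov, cbind(pick, class = as.integer(cl)))
    }
    # extract patches scene by scene
    X <- matrix(NA_real_, nrow(prov), patch_size^2)
    for (s in unique(prov[, 1L])) {
      rows <- which(prov[, 1L] == s)
      img <- scenes[[s]]$image
      H <- nrow(img)
      rc <- cbind(((prov[rows, 2L] - 1L) %% H) + 1L,
                  ((prov[rows, 2L] - 1L) %/% H) + 1L)
      m <- (patch_size - 1L) %/% 2L
      off <- -m:m
      ridx <- outer(rc[, 1L], off, `+`); cidx <- outer(rc[, 2L], off, `+`)
      ridx[] <- .reflect_index(as.integer(ridx), H)
      cidx[] <- .reflect_index(as.integer(cidx), ncol(img))
      for (v in seq_len(patch_size)) {
        cc <- cidx[, v]
        for (u in seq_len(patch_size)) {
          X[rows, u + (v - 1L) * patch_size] <- img[ridx[, u] + (cc - 1L) * H]
        }
      }
    }
    list(x = X, y = prov[, 3L], provenance = prov)
  })
}

#' Canonical desk-scale benchmark suite
#'
#' Twenty 64x64 scenes under the default [scene_config()] conditions, split
#' 70/30 by scene into 14 training and 6 test scenes. Per-scene seeds are
#' derived deterministically from the suite seed, so the same seed
#' regenerates the identical suite.
#'
#' @param seed Integer suite seed.
#' @param n_scenes Total number of scenes (70/30 split by scene).
#' @param image_size Scene side in pixels.
#' @return List with `train` and `test` lists of `"fbcnn_scene"` objects.
#' @export
benchmark_suite <- function(seed, n_scenes = 20L, image_size = 64L) {
  scenes <- lapply(seq_len(n_scenes), function(i) {
    generate_scene(scene_config(image_size = image_size,
                                seed = .derive_seed(seed, 100L + i)))
  })
  n_train <- round(0.7 * n_scenes)
  list(train = scenes[seq_len(n_train)],
       test = scenes[(n_train + 1L):n_scenes])
}
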