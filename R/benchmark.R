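#' Run the canonical desk-scale segmentation benchmark
#'
#' The package's standard end-to-end evaluation: generate the
#' [benchmark_suite()] (20 scenes 64x64, 14 train / 6 test), sample a
#' class-balanced 25x25 patch dataset from the training scenes, fit the
#' default classifier, and segment every test scene with the default
#' [seg_config()], scoring each stage against the known masks. All
#' randomness derives from the single suite seed, so a repeated run with the
#' same seed is byte-identical.
#'
#' @param seed Integer master seed.
#' @param n_per_class Training patches per class sampled from the training
#'   scenes.
#' @param control Training control; defaults to [train_control()] with a
#'   seed derived from `seed`.
#' @param config Segmentation configuration.
#' @return List with `fit` (the trained classifier), `metrics` (per-scene x
#'   per-stage Dice/IoU/accuracy array), `summary` (named vector of means),
#'   `masks` (per-scene initial/threshold/final masks), `train_accuracy`,
#'   and `suite`.
#' @export
run_benchmark <- function(seed, n_per_class = 1500L, control = NULL,
                          config = seg_config()) {
  suite <- benchmark_suite(seed)
  ds <- make_patch_dataset(suite$train, n_per_class = n_per_class,
                           patch_size = config$patch_size,
                           seed = .derive_seed(seed, 7L))
  if (is.null(control)) control <- train_control(seed = .derive_seed(seed, 8L))
  fit <- fbcnn_fit(ds$x, ds$y,
                   input_shape = c(config$patch_size, config$patch_size, 1L),
                   control = control)
  train_accuracy <- mean(predict(fit, ds$x) == ds$y)
  outs <- lapply(suite$test, function(sc)
    segment_image(fit, sc$image, config, truth = sc$mask))
  metrics <- array(NA_real_,
                   dim = c(length(outs), 3L, 3L),
                   dimnames = list(NULL, c("initial", "threshold", "final"),
                                   c("dice", "iou", "accuracy")))
  for (i in seq_along(outs)) metrics[i, , ] <- outs[[i]]$metrics
  summary <- c(mean_initial_dice = mean(metrics[, "initial", "dice"]),
               mean_final_dice = mean(metrics[, "final", "dice"]),
               mean_final_iou = mean(metrics[, "final", "iou"]),
               mean_final_accuracy = mean(metrics[, "final", "accuracy"]),
               train_accuracy = train_accuracy)
  list(fit = fit, metrics = metrics, summary = summary,
       masks = lapply(outs, function(o)
         list(initial = o$initial_mask, threshold = o$threshold_mask,
              final = o$final_mask)),
       train_accuracy = train_accuracy, suite = suite)
}
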