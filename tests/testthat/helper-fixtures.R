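# Small, fast scene used by most image-level tests.
small_scene_config <- function(...) {
  args <- list(...)
  defaults <- list(n_leaves = 9, image_size = c(120, 210),
                   panel_size = c(28, 40), seed = 42)
  do.call(scene_config, utils::modifyList(defaults, args))
}

# A scene with every stochastic or shape distortion disabled: the forward
# model is then exactly invertible through calibration.
clean_scene_config <- function(...) {
  small_scene_config(scatter_sd = 0, offset_sd = 0, noise_sd = 0,
                     vein_contrast = 1, gradient_amp = 0, ...)
}

# Toy regression problem: target built from the first one or two columns.
toy_regression <- function(n, p, seed, noise) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- 2 * x[, 1] + (if (p >= 2) x[, 2] else 0) + rnorm(n, 0, noise)
  })
  list(x = x, y = y)
}

# Wrap an arbitrary feature matrix + target(s) as a normalized
# feature_table so the selection algorithms can run on toy problems.
toy_feature_table <- function(x, chl_ab, car = chl_ab) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  ft <- structure(list(features = x,
                       targets = data.frame(chl_ab = chl_ab, car = car),
                       mode = "as_printed", normalized = FALSE,
                       center = NULL, scale = NULL),
                  class = "feature_table")
  normalize_features(ft)
}

# Random valid band vectors: reflectance-like, bounded away from the VI
# denominator guards.
random_band_matrix <- function(n, seed = 1) {
  withr::with_seed(seed, {
    m <- cbind(Blue = runif(n, 0.02, 0.15), Green = runif(n, 0.1, 0.4),
               Red = runif(n, 0.05, 0.35), Edge1 = runif(n, 0.2, 0.5),
               Edge2 = runif(n, 0.45, 0.6), NIR = runif(n, 0.62, 0.8))
    m
  })
}

# Segment + layer-assign a rendered scene the way the pipeline does.
segment_scene <- function(scene) {
  refl <- calibrate(scene$image, scene$panel, scene$config$panel_reflectance)
  leaves <- segment_leaves(refl, exclude = scene$panel)
  leaves <- assign_layers(leaves, scene$truth$label_map,
                          scene$truth$leaf_table)
  list(refl = refl, leaves = leaves,
       targets = scene$truth$leaf_table[
         match(leaves$truth_id, scene$truth$leaf_table$leaf_id), ])
}
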