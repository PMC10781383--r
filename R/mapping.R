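#' Pixel-wise pigment prediction map
#'
#' Applies a fitted [fit_model()] pigment model to every leaf pixel of a
#' reflectance image: the model's variable subset is computed per pixel,
#' the stored training normalization is applied, and the model predicts.
#' The image must carry the same preprocessing the model was trained on
#' (pass the MSC-corrected cube for an MSC-trained model). Pixels with a
#' masked index value, or predictions outside the training-target range
#' widened by 20% on each side, are flagged as outliers rather than
#' silently dropped.
#'
#' @param img Reflectance [multiband_image()] (MSC-corrected or original,
#'   matching the model's training data).
#' @param leaves A `leaf_set`.
#' @param model A `pigment_model`.
#' @param outlier_expand Range-widening fraction of the outlier rule.
#' @return A `pigment_map`: list with `values` (H x W, NA outside leaves),
#'   `outlier` (logical H x W), `target`, `family`.
#' @export
predict_map <- function(img, leaves, model, outlier_expand = 0.2) {
  stopifnot(inherits(img, "multiband_image"), inherits(leaves, "leaf_set"),
            inherits(model, "pigment_model"))
  idx <- which(leaves$labels > 0)
  bands <- vapply(1:6, function(b) img$data[, , b][idx], numeric(length(idx)))
  colnames(bands) <- names(band_centers)
  feats <- matrix(NA_real_, length(idx), length(model$subset),
                  dimnames = list(NULL, model$subset))
  for (v in model$subset) {
    feats[, v] <- if (v %in% band_names) {
      bands[, which(band_names == v)]
    } else {
      compute_vi(v, bands, mode = model$mode)
    }
  }
  masked <- !stats::complete.cases(feats)
  z <- sweep(sweep(feats, 2, model$center), 2, model$scale, "/")
  pred <- rep(NA_real_, length(idx))
  ok <- !masked
  if (any(ok)) pred[ok] <- model$model$predict(z[ok, , drop = FALSE])
  rng <- model$y_range
  wid <- outlier_expand * diff(rng)
  out_of_range <- !is.na(pred) & (pred < rng[1] - wid | pred > rng[2] + wid)
  H <- nrow(leaves$labels); W <- ncol(leaves$labels)
  values <- matrix(NA_real_, H, W); values[idx] <- pred
  outlier <- matrix(FALSE, H, W); outlier[idx] <- masked | out_of_range
  n_flag <- sum(masked | out_of_range)
  if (n_flag) message(n_flag, " pixel(s) flagged as outliers")
  structure(list(values = values, outlier = outlier,
                 target = model$target, family = model$family),
            class = "pigment_map")
}

#' @export
print.pigment_map <- function(x, ...) {
  n <- sum(!is.na(x$values))
  cat(sprintf("pigment_map: %s (%s model), %d leaf pixels, %d outliers\n",
              x$target, x$family, n, sum(x$outlier)))
  invisible(x)
}

#' Per-layer summaries of a pigment map
#'
#' For every canopy layer: a frequency histogram of the non-outlier pixel
#' predictions (50 equal-width bins over the layer's range), the pixel mean
#' (the "green line"), and the mean laboratory value of that layer's leaves
#' (the "red line").
#'
#' @param map A `pigment_map`.
#' @param leaves A `leaf_set` with `layer` assigned (see [assign_layers()]).
#' @param lab Per-leaf lab table with `layer` and the target column
#'   (`chl_ab` or `car`).
#' @param bins Number of histogram bins.
#' @return A `layer_summary` list, one element per non-empty layer, each
#'   with `layer`, `breaks`, `counts`, `pixel_mean`, `lab_mean`, `n_pixels`.
#' @export
summarize_layers <- function(map, leaves, lab, bins = 50) {
  stopifnot(inherits(map, "pigment_map"))
  if (all(is.na(leaves$layer))) stop("leaf_set has no layer labels", call. = FALSE)
  layers <- c("upper", "middle", "lower")
  out <- list()
  for (ly in layers) {
    leaf_ids <- which(leaves$layer == ly)
    if (!length(leaf_ids)) {
      warning("empty layer omitted: ", ly, call. = FALSE)
      next
    }
    sel <- leaves$labels %in% leaf_ids & !map$outlier & !is.na(map$values)
    px <- map$values[sel]
    if (!length(px)) {
      warning("layer with no usable pixels omitted: ", ly, call. = FALSE)
      next
    }
    h <- graphics::hist(px, breaks = seq(min(px), max(px), length.out = bins + 1),
                        plot = FALSE)
    out[[ly]] <- list(layer = ly, breaks = h$breaks, counts = h$counts,
                      pixel_mean = mean(px),
                      lab_mean = mean(lab[[map$target]][lab$layer == ly]),
                      n_pixels = length(px))
  }
  structure(out, class = "layer_summary")
}

#' @export
print.layer_summary <- function(x, ...) {
  for (s in x) {
    cat(sprintf("%-7s pixels %6d  pixel mean %7.3f  lab mean %7.3f\n",
                s$layer, s$n_pixels, s$pixel_mean, s$lab_mean))
  }
  invisible(x)
}

#' @export
plot.layer_summary <- function(x, ...) {
  op <- graphics::par(mfrow = c(length(x), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in x) {
    mids <- (s$breaks[-1] + s$breaks[-length(s$breaks)]) / 2
    graphics::plot(mids, s$counts, type = "h", lwd = 3,
                   xlab = "predicted content (ug/cm2)", ylab = "frequency",
                   main = s$layer, ...)
    graphics::abline(v = s$lab_mean, col = "red", lwd = 2)
    graphics::abline(v = s$pixel_mean, col = "darkgreen", lwd = 2)
  }
  invisible(x)
}
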