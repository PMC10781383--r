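#' Ideal spectrum for multiplicative scatter correction
#'
#' The MSC reference ("ideal") spectrum of a group image is the band-wise
#' mean over all leaf pixels of that image.
#'
#' @param leaves A `leaf_set` (its label map defines the leaf pixels).
#' @param img The reflectance [multiband_image()] the labels refer to.
#' @return An `ideal_spectrum`: list with `spectrum` (length 6), `n_pixels`.
#' @export
ideal_spectrum <- function(leaves, img) {
  stopifnot(inherits(leaves, "leaf_set"), inherits(img, "multiband_image"))
  idx <- which(leaves$labels > 0)
  if (!length(idx)) stop("no leaf pixels: cannot form ideal spectrum", call. = FALSE)
  sp <- vapply(1:6, function(b) mean(img$data[, , b][idx]), 0)
  names(sp) <- names(band_centers)
  if (stats::sd(sp) < 1e-12) {
    stop("ideal spectrum is constant across bands", call. = FALSE)
  }
  structure(list(spectrum = sp, n_pixels = length(idx)),
            class = "ideal_spectrum")
}

#' Multiplicative scatter correction
#'
#' Each spectrum is regressed on the ideal spectrum across the six bands,
#' `spectrum ~ a + b * ideal` (ordinary least squares), and the fitted
#' affine distortion is inverted: `corrected = (spectrum - a) / b`. This
#' removes per-leaf multiplicative and additive scatter effects (specular
#' reflection, leaf inclination) and exactly inverts any affine distortion
#' with positive gain. Negative corrected reflectances are permitted (the
#' correction is affine); vegetation-index guards handle them downstream.
#'
#' @param spectra Length-6 vector or n x 6 matrix of spectra.
#' @param ideal An [ideal_spectrum()] (or length-6 numeric vector).
#' @return Corrected spectra, same shape as the input.
#' @export
msc_correct <- function(spectra, ideal) {
  iv <- if (inherits(ideal, "ideal_spectrum")) ideal$spectrum else as.numeric(ideal)
  if (stats::sd(iv) < 1e-12) stop("ideal spectrum is constant", call. = FALSE)
  one_row <- is.null(dim(spectra))
  s <- if (one_row) matrix(spectra, nrow = 1) else as.matrix(spectra)
  if (ncol(s) != 6) stop("spectra must have 6 bands", call. = FALSE)
  im <- mean(iv)
  ic <- iv - im
  denom <- sum(ic^2)
  b <- as.vector(s %*% ic) / denom          # per-row OLS slope on the ideal
  a <- rowMeans(s) - b * im
  if (any(abs(b) < 1e-8)) {
    stop("degenerate MSC fit: spectrum uncorrelated with ideal", call. = FALSE)
  }
  out <- (s - a) / b
  colnames(out) <- names(band_centers)
  if (one_row) out[1, ] else out
}

#' MSC-correct a whole reflectance image over the leaf mask
#'
#' Applies [msc_correct()] pixel-wise (shared group ideal) to all leaf
#' pixels; background and panel pixels are left untouched.
#'
#' @param img Reflectance [multiband_image()].
#' @param leaves A `leaf_set`.
#' @param ideal An [ideal_spectrum()]; computed from `img` if missing.
#' @return The corrected reflectance `multiband_image`.
#' @export
msc_correct_image <- function(img, leaves, ideal = ideal_spectrum(leaves, img)) {
  idx <- which(leaves$labels > 0)
  s <- vapply(1:6, function(b) img$data[, , b][idx], numeric(length(idx)))
  cs <- msc_correct(s, ideal)
  out <- img$data
  for (b in 1:6) {
    plane <- out[, , b]
    plane[idx] <- cs[, b]
    out[, , b] <- plane
  }
  multiband_image(out, bands = img$bands, kind = "reflectance",
                  bit_depth = img$bit_depth)
}
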