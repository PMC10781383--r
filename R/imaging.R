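#' Multiband image container
#'
#' A light wrapper around an H x W x 6 numeric array with band metadata and
#' a kind flag distinguishing raw sensor counts from calibrated reflectance.
#' Counts are held as floating-point values in \[0, 65535\] (quantisation to
#' integers happens only on 16-bit TIFF export).
#'
#' @param data H x W x 6 array.
#' @param bands Band centres, nm.
#' @param kind `"counts"` or `"reflectance"`.
#' @param bit_depth Nominal sensor bit depth.
#' @return A `multiband_image`.
#' @export
multiband_image <- function(data, bands = band_centers,
                            kind = c("counts", "reflectance"),
                            bit_depth = 16L) {
  kind <- match.arg(kind)
  d <- dim(data)
  if (length(d) != 3 || d[3] != 6) stop("data must be H x W x 6", call. = FALSE)
  if (any(!is.finite(data))) stop("image values must be finite", call. = FALSE)
  if (kind == "counts" && (min(data) < 0 || max(data) > 65535)) {
    stop("counts must lie in [0, 65535]", call. = FALSE)
  }
  structure(list(data = data, bands = bands, kind = kind,
                 bit_depth = bit_depth), class = "multiband_image")
}

#' @export
print.multiband_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("multiband_image: %d x %d px, %d bands (%s), kind = %s\n",
              d[1], d[2], d[3], paste(x$bands, collapse = "/"), x$kind))
  invisible(x)
}

#' Read or write a multiband TIFF
#'
#' Counts images are written as 16-bit (integer-quantised), reflectance
#' images as 32-bit float. `read_multiband_tiff` rescales 16-bit data back
#' to counts.
#'
#' @param img A [multiband_image()].
#' @param path TIFF path.
#' @export
write_multiband_tiff <- function(img, path) {
  stopifnot(inherits(img, "multiband_image"))
  planes <- lapply(1:6, function(b) img$data[, , b])  # one page per band
  if (img$kind == "counts") {
    tiff::writeTIFF(lapply(planes, `/`, 65535), path, bits.per.sample = 16L)
  } else {
    rng <- range(img$data)
    scl <- if (rng[2] > 1 || rng[1] < 0) max(abs(rng)) else 1
    tiff::writeTIFF(lapply(planes, function(p) pmax(p / scl, 0)), path,
                    bits.per.sample = 32L)
  }
  invisible(path)
}

#' @rdname write_multiband_tiff
#' @param kind Interpretation of the stored values.
#' @export
read_multiband_tiff <- function(path, kind = c("counts", "reflectance")) {
  kind <- match.arg(kind)
  x <- simplify2array(tiff::readTIFF(path, all = TRUE))
  if (kind == "counts") x <- x * 65535
  multiband_image(x, kind = kind)
}

#' Flat-field radiometric calibration against a reference panel
#'
#' Per band, reflectance is the ratio of pixel counts to the mean counts
#' over the panel region, scaled by the panel's known reflectance:
#' `R = counts / mean(panel counts) * panel_reflectance`. This emulates the
#' usual flat-field workflow with a panel-ratio formula and is invariant to
#' a global illumination rescaling.
#'
#' @param img A counts [multiband_image()].
#' @param panel_region Rectangle `c(r0, r1, c0, c1)` (row/col bounds,
#'   inclusive) of the panel.
#' @param panel_reflectance Per-band panel reflectance fraction.
#' @return A reflectance `multiband_image`.
#' @export
calibrate <- function(img, panel_region, panel_reflectance = rep(0.99, 6)) {
  stopifnot(inherits(img, "multiband_image"))
  if (img$kind != "counts") stop("calibrate expects a counts image", call. = FALSE)
  p <- as.integer(panel_region)
  d <- dim(img$data)
  if (p[1] < 1 || p[2] > d[1] || p[3] < 1 || p[4] > d[2] ||
      p[1] > p[2] || p[3] > p[4]) {
    stop("panel_region must be a nonempty rectangle inside the image",
         call. = FALSE)
  }
  out <- img$data
  for (b in 1:6) {
    pm <- mean(img$data[p[1]:p[2], p[3]:p[4], b])
    if (pm <= 0) stop("zero panel mean in band ", b, call. = FALSE)
    out[, , b] <- img$data[, , b] / pm * panel_reflectance[b]
  }
  multiband_image(out, bands = img$bands, kind = "reflectance",
                  bit_depth = img$bit_depth)
}

# 8-connected component labelling of a logical matrix via an igraph
# pixel-adjacency graph; labels renumbered 1..K by descending area.
.label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, H, W))
  id <- integer(H * W); id[idx] <- seq_along(idx)
  r <- (idx - 1L) %% H + 1L; cc <- (idx - 1L) %/% H + 1L
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    nb <- (c2[ok] - 1L) * H + r2[ok]
    has <- id[nb] > 0L
    edges[[length(edges) + 1L]] <- cbind(id[idx[ok][has]], id[nb[has]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # renumber by descending component size (stable for ties)
  size <- tabulate(comp)
  newlab <- integer(length(size))
  newlab[order(-size)] <- seq_along(size)
  out <- matrix(0L, H, W)
  out[idx] <- newlab[comp]
  out
}

#' Segment and label leaves by NIR reflectance threshold
#'
#' Pixels with 840-nm reflectance strictly above `threshold` form the leaf
#' mask; 8-connected components below `min_area` pixels are removed and the
#' rest are labelled 1..K by descending area. Per-leaf mean spectra are the
#' band-wise means over member pixels.
#'
#' @param img A reflectance [multiband_image()].
#' @param threshold 840-nm reflectance threshold (default 0.25; the
#'   boundary value itself is background).
#' @param min_area Minimum component area in pixels.
#' @param exclude Optional rectangle `c(r0, r1, c0, c1)` removed from the
#'   mask before labelling — the reference panel is bright in the NIR and
#'   would otherwise be segmented as a leaf.
#' @return A `leaf_set`: list with `labels` (H x W integer matrix, 0 =
#'   background), `spectra` (K x 6 matrix), `area` (pixel counts) and
#'   `layer` (NA until assigned).
#' @export
segment_leaves <- function(img, threshold = 0.25, min_area = 50,
                           exclude = NULL) {
  stopifnot(inherits(img, "multiband_image"))
  if (img$kind != "reflectance") {
    stop("segment_leaves expects a reflectance image", call. = FALSE)
  }
  mask <- img$data[, , 6] > threshold
  if (!is.null(exclude)) {
    e <- as.integer(exclude)
    mask[e[1]:e[2], e[3]:e[4]] <- FALSE
  }
  lab <- .label_components(mask)
  if (max(lab) > 0) {
    area <- tabulate(lab[lab > 0])
    drop <- which(area < min_area)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      keep <- setdiff(seq_along(area), drop)
      relab <- integer(length(area)); relab[keep] <- seq_along(keep)
      lab[lab > 0] <- relab[lab[lab > 0]]
      area <- area[keep]
    }
  }
  k <- max(lab)
  if (k == 0) {
    warning("empty leaf mask: no pixels above threshold", call. = FALSE)
    return(structure(list(labels = lab,
                          spectra = matrix(numeric(0), 0, 6,
                                           dimnames = list(NULL, names(band_centers))),
                          area = integer(0), layer = character(0)),
                     class = "leaf_set"))
  }
  spectra <- leaf_mean_spectra(lab, img)
  structure(list(labels = lab, spectra = spectra,
                 area = tabulate(lab[lab > 0], k),
                 layer = rep(NA_character_, k)),
            class = "leaf_set")
}

#' @export
print.leaf_set <- function(x, ...) {
  cat(sprintf("leaf_set: %d leaves, %d leaf pixels\n",
              nrow(x$spectra), sum(x$area)))
  invisible(x)
}

#' Per-leaf mean spectra from a label map
#'
#' @param labels H x W integer label matrix (0 = background).
#' @param img A [multiband_image()] of matching size.
#' @return K x 6 matrix of mean reflectances.
#' @export
leaf_mean_spectra <- function(labels, img) {
  k <- max(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  out <- vapply(1:6, function(b) {
    plane <- img$data[, , b]
    as.vector(tapply(plane[idx], lab, mean))
  }, numeric(k))
  out <- matrix(out, nrow = k, dimnames = list(NULL, names(band_centers)))
  out
}

#' Match segmented leaves to ground-truth layers
#'
#' Assigns each segmented leaf the layer (and optionally identity) of the
#' ground-truth leaf its pixels overlap most.
#'
#' @param leaves A `leaf_set`.
#' @param truth_labels Ground-truth label matrix.
#' @param truth_table Ground-truth per-leaf table with `leaf_id` and `layer`.
#' @return The `leaf_set` with `layer` filled and a `truth_id` vector added.
#' @export
assign_layers <- function(leaves, truth_labels, truth_table) {
  k <- nrow(leaves$spectra)
  truth_id <- integer(k)
  for (i in seq_len(k)) {
    ov <- truth_labels[leaves$labels == i]
    ov <- ov[ov > 0]
    truth_id[i] <- if (length(ov)) as.integer(names(which.max(table(ov)))) else NA_integer_
  }
  leaves$truth_id <- truth_id
  leaves$layer <- truth_table$layer[match(truth_id, truth_table$leaf_id)]
  leaves
}

#' Write segmentation outputs
#'
#' Label map as single-band uint16 TIFF and per-leaf spectra as CSV
#' (leaf_id, area_px, R450..R840).
#'
#' @param leaves A `leaf_set`.
#' @param label_path,spectra_path Output paths (NULL skips either).
#' @export
write_leaf_set <- function(leaves, label_path = NULL, spectra_path = NULL) {
  if (!is.null(label_path)) {
    tiff::writeTIFF(leaves$labels / 65535, label_path, bits.per.sample = 16L)
  }
  if (!is.null(spectra_path)) {
    df <- data.frame(leaf_id = seq_len(nrow(leaves$spectra)),
                     area_px = leaves$area)
    sp <- leaves$spectra
    colnames(sp) <- paste0("R", band_centers)
    utils::write.csv(cbind(df, sp), spectra_path, row.names = FALSE)
  }
  invisible(leaves)
}
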