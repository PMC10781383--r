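#' Build the 32-variable pseudo-hyper-spectrum feature table
#'
#' Augments the six band reflectances with the 26 registry vegetation
#' indices, giving the fixed 32-column variable set (B1..B6 then the VI
#' abbreviations in registry order). Samples for which any index is masked
#' (near-zero denominator) are dropped with a message.
#'
#' @param spectra n x 6 matrix of band reflectances (columns 450..840 nm).
#' @param targets data.frame with columns `chl_ab` and `car` (ug/cm2), one
#'   row per spectrum; may also carry `leaf_id` and `layer`.
#' @param mode VI formula mode, see [vi_registry()].
#' @return A `feature_table`: list with `features` (n x 32 matrix),
#'   `targets`, `mode`, `normalized` flag and (after [normalize_features()])
#'   `center`/`scale` vectors.
#' @export
build_feature_table <- function(spectra, targets, mode = c("as_printed", "canonical")) {
  mode <- match.arg(mode)
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != 6) stop("spectra must have 6 band columns", call. = FALSE)
  if (nrow(spectra) != nrow(targets)) {
    stop("spectra and targets must have the same number of rows", call. = FALSE)
  }
  if (!all(c("chl_ab", "car") %in% names(targets))) {
    stop("targets must contain chl_ab and car columns", call. = FALSE)
  }
  colnames(spectra) <- names(band_centers)
  vis <- vapply(vi_names(), function(nm) compute_vi(nm, spectra, mode),
                numeric(nrow(spectra)))
  if (nrow(spectra) == 1) vis <- matrix(vis, nrow = 1, dimnames = list(NULL, vi_names()))
  feats <- cbind(spectra, vis)
  colnames(feats) <- c(band_names, vi_names())
  keep <- stats::complete.cases(feats)
  if (any(!keep)) {
    message(sum(!keep), " sample(s) dropped: masked vegetation index value")
  }
  structure(list(features = feats[keep, , drop = FALSE],
                 targets = targets[keep, , drop = FALSE],
                 mode = mode, normalized = FALSE,
                 center = NULL, scale = NULL),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d variables (mode %s, %s)\n",
              nrow(x$features), ncol(x$features), x$mode,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  cbind(as.data.frame(x$features), x$targets)
}

#' Standardize feature columns
#'
#' Z-scores every feature column (sample SD, n - 1 denominator) and stores
#' the centring/scaling parameters so they can be re-applied to new samples
#' or image pixels at mapping time.
#'
#' @param table A `feature_table`.
#' @return The normalized `feature_table`, with `center` and `scale` set.
#' @export
normalize_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$features) < 2) stop("need >= 2 samples", call. = FALSE)
  ctr <- colMeans(table$features)
  scl <- apply(table$features, 2, stats::sd)
  zero <- scl < 1e-12
  if (any(zero)) {
    stop("zero-variance feature column(s): ",
         paste(colnames(table$features)[zero], collapse = ", "), call. = FALSE)
  }
  table$features <- sweep(sweep(table$features, 2, ctr), 2, scl, "/")
  table$normalized <- TRUE
  table$center <- ctr
  table$scale <- scl
  table
}

#' Apply stored normalization parameters to new feature rows
#'
#' @param table A normalized `feature_table` (source of the parameters).
#' @param newdata Matrix with columns named after (a subset of) the table's
#'   feature columns.
#' @return The standardized matrix.
#' @export
apply_normalization <- function(table, newdata) {
  stopifnot(inherits(table, "feature_table"), isTRUE(table$normalized))
  nm <- colnames(newdata)
  if (!all(nm %in% names(table$center))) {
    stop("newdata has columns without stored normalization parameters",
         call. = FALSE)
  }
  sweep(sweep(newdata, 2, table$center[nm]), 2, table$scale[nm], "/")
}

#' Rank variables by absolute Pearson correlation with a pigment target
#'
#' @param table A `feature_table`.
#' @param target `"chl_ab"` or `"car"`.
#' @return A `correlation_ranking` data.frame (variable, r, abs_r, rank),
#'   ordered by descending `|r|`; ties keep registry order.
#' @export
rank_by_correlation <- function(table, target = c("chl_ab", "car")) {
  stopifnot(inherits(table, "feature_table"))
  target <- match.arg(target)
  y <- table$targets[[target]]
  if (length(y) < 3) stop("need >= 3 samples", call. = FALSE)
  if (stats::sd(y) < 1e-12) stop("zero-variance target", call. = FALSE)
  r <- as.vector(stats::cor(table$features, y))
  ord <- order(-abs(r))  # order() is stable: ties keep registry order
  out <- data.frame(variable = colnames(table$features)[ord],
                    r = r[ord], abs_r = abs(r)[ord],
                    rank = seq_along(r), target = target,
                    row.names = NULL)
  class(out) <- c("correlation_ranking", "data.frame")
  out
}

#' Write a feature table to CSV
#'
#' Header row is the fixed registry variable order followed by the target
#' columns.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
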