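#' Prediction-model specification
#'
#' The two reported model families: partial least squares regression
#' (`"plsr"`) and epsilon-insensitive support vector regression with an RBF
#' kernel (`"svr_rbf"`). Hyperparameters are chosen by grid search:
#' latent factors `1..min(15, p)` for PLSR; for SVR, `cost` spanning
#' \[0.1, 10\] and `gamma` spanning \[0.005, 1\] on logarithmic steps.
#'
#' @param family `"plsr"` or `"svr_rbf"`.
#' @param grid Optional custom grid (data.frame `ncomp`, or `cost`+`gamma`).
#' @param seed Seed for tuning-fold assignments.
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("plsr", "svr_rbf"), grid = NULL, seed = 1) {
  family <- match.arg(family)
  kind <- if (family == "plsr") "pls" else "svm_rbf"
  ls <- learner_spec(kind, grid = grid, folds = 5, repeats = 1,
                     tuning = "grid", seed = seed)
  structure(list(family = family, kind = kind, grid = ls$grid, seed = seed),
            class = "model_spec")
}

#' Tune, fit and predict
#'
#' Hyperparameters are selected by 5-fold grid-search cross-validation on
#' the training rows only; the model is then refitted on all training rows
#' and applied to the test rows. The SVR standardizes the target inside the
#' training set (epsilon = 0.1 on the standardized scale) and restores the
#' original scale for reporting; PLSR centres only.
#'
#' @param spec A [model_spec()].
#' @param x_train,y_train Training features (already normalized) and target.
#' @param x_test Feature rows to predict.
#' @return List with `predictions`, `params` (chosen grid row) and `model`.
#' @export
fit_predict <- function(spec, x_train, y_train, x_test) {
  stopifnot(inherits(spec, "model_spec"))
  x_train <- .as_matrix_named(x_train)
  if (!nrow(x_train)) stop("empty training set", call. = FALSE)
  tuner <- learner_spec(spec$kind, grid = spec$grid, folds = min(5, nrow(x_train)),
                        repeats = 1, tuning = "grid", seed = spec$seed)
  sc <- cv_rmse(x_train, y_train, tuner)
  pars <- attr(sc, "best_params")
  m <- .fit_learner(spec$kind, x_train, y_train, pars)
  x_test <- .as_matrix_named(x_test)[, colnames(x_train), drop = FALSE]
  list(predictions = m$predict(x_test), params = pars, model = m)
}

#' Fit a final prediction model on a feature table
#'
#' Convenience wrapper used for pixel mapping: tunes and fits on the whole
#' (normalized) table restricted to a variable subset and keeps the
#' normalization parameters needed to score new pixels.
#'
#' @param spec A [model_spec()].
#' @param table A normalized `feature_table`.
#' @param target `"chl_ab"` or `"car"`.
#' @param subset Variable names (default: all columns).
#' @return A `pigment_model`: list with `model`, `params`, `subset`,
#'   `target`, `center`/`scale` for the subset and the training-target range.
#' @export
fit_model <- function(spec, table, target = c("chl_ab", "car"),
                      subset = colnames(table$features)) {
  stopifnot(inherits(table, "feature_table"), isTRUE(table$normalized))
  target <- match.arg(target)
  y <- table$targets[[target]]
  fp <- fit_predict(spec, table$features[, subset, drop = FALSE], y,
                    table$features[, subset, drop = FALSE])
  structure(list(model = fp$model, params = fp$params, family = spec$family,
                 subset = subset, target = target,
                 center = table$center[subset], scale = table$scale[subset],
                 mode = table$mode, y_range = range(y)),
            class = "pigment_model")
}

#' @export
print.pigment_model <- function(x, ...) {
  cat(sprintf("pigment_model: %s for %s on %d variables (%s)\n",
              x$family, x$target, length(x$subset),
              paste(x$subset, collapse = " ")))
  invisible(x)
}

#' Leave-one-out cross-validation of a prediction model
#'
#' One fold per sample. Within each fold, feature normalization is redone
#' from the training rows only, hyperparameters are re-tuned, and the held
#' out sample is predicted by a model that never saw it. The pooled held
#' out predictions give the reported R2 and RMSE.
#'
#' @param spec A [model_spec()].
#' @param table A `feature_table` (raw or normalized; the stored parameters
#'   are used to reconstruct raw values so fold-wise normalization is
#'   leak-free).
#' @param target `"chl_ab"` or `"car"`.
#' @param subset Variable names to use (default: all).
#' @return An `eval_report`: list with `r2`, `rmse`, `predictions`
#'   (data.frame measured/predicted), `params` per fold, `family`, `subset`.
#' @export
loocv <- function(spec, table, target = c("chl_ab", "car"),
                  subset = colnames(table$features)) {
  stopifnot(inherits(table, "feature_table"))
  target <- match.arg(target)
  y <- table$targets[[target]]
  n <- length(y)
  if (n < 3) stop("LOOCV needs at least 3 samples", call. = FALSE)
  feats <- table$features[, subset, drop = FALSE]
  if (isTRUE(table$normalized)) {  # reconstruct raw values
    feats <- sweep(sweep(feats, 2, table$scale[subset], "*"), 2,
                   table$center[subset], "+")
  }
  preds <- numeric(n)
  params <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- feats[-i, , drop = FALSE]
    ctr <- colMeans(tr); scl <- apply(tr, 2, stats::sd)
    scl[scl < 1e-12] <- 1
    ztr <- sweep(sweep(tr, 2, ctr), 2, scl, "/")
    zte <- sweep(sweep(feats[i, , drop = FALSE], 2, ctr), 2, scl, "/")
    fp <- fit_predict(spec, ztr, y[-i], zte)
    preds[i] <- fp$predictions
    params[[i]] <- fp$params
  }
  structure(list(family = spec$family, target = target, subset = subset,
                 n = n, r2 = r_squared(y, preds),
                 rmse = rmse(y, preds),
                 predictions = data.frame(measured = y, predicted = preds),
                 params = params),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %s for %s, LOOCV over n = %d\n",
              x$family, x$target, x$n))
  cat(sprintf("  R2 = %.3f, RMSE = %.3f (%d variables)\n",
              x$r2, x$rmse, length(x$subset)))
  invisible(x)
}

#' @export
plot.eval_report <- function(x, ...) {
  graphics::plot(x$predictions$measured, x$predictions$predicted, pch = 16,
                 xlab = sprintf("measured %s (ug/cm2)", x$target),
                 ylab = "predicted (ug/cm2)",
                 main = sprintf("%s LOOCV: R2 = %.3f, RMSE = %.3f",
                                x$family, x$r2, x$rmse), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Write an evaluation report
#'
#' JSON summary plus a CSV of the per-sample held-out predictions.
#'
#' @param x An `eval_report`.
#' @param json_path,csv_path Output paths (NULL skips either).
#' @export
write_eval_report <- function(x, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(family = x$family, target = x$target,
                              n = x$n, r2 = x$r2, rmse = x$rmse,
                              subset = x$subset),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(x$predictions, csv_path, row.names = FALSE)
  }
  invisible(x)
}

#' Coefficient of determination
#'
#' Default is the squared Pearson correlation between measured and
#' predicted values (invariant to affine rescaling of the predictions).
#' `"one_minus_rss"` gives `1 - SS_res / SS_tot`. `"as_printed"` evaluates
#' the literal printed form `sum((y - Y)^2) / (sum(y - ybar) * sum(Y -
#' Ybar))`, whose denominator terms are identically zero — it is exposed
#' only so the corrupted typeset formula can be inspected, and returns a
#' non-finite value.
#'
#' @param measured,predicted Numeric vectors of equal length (n >= 2).
#' @param method `"correlation"`, `"one_minus_rss"` or `"as_printed"`.
#' @return R2 value.
#' @export
r_squared <- function(measured, predicted,
                      method = c("correlation", "one_minus_rss", "as_printed")) {
  method <- match.arg(method)
  if (length(measured) != length(predicted)) stop("length mismatch", call. = FALSE)
  if (length(measured) < 2) stop("need n >= 2", call. = FALSE)
  if (method == "correlation") {
    if (stats::sd(measured) < 1e-12 || stats::sd(predicted) < 1e-12) {
      stop("zero variance in measured or predicted values", call. = FALSE)
    }
    stats::cor(measured, predicted)^2
  } else if (method == "one_minus_rss") {
    if (stats::sd(measured) < 1e-12) stop("zero variance in measured values", call. = FALSE)
    1 - sum((measured - predicted)^2) / sum((measured - mean(measured))^2)
  } else {
    sum((measured - predicted)^2) /
      (sum(measured - mean(measured)) * sum(predicted - mean(predicted)))
  }
}

#' Root mean square error
#'
#' Default is the root mean squared residual
#' `sqrt(mean((y_i - Y_i)^2))`. `"as_printed"` evaluates the literal
#' printed variant `sqrt(mean((y_i - Ybar)^2))`, which compares each
#' measurement to the mean prediction; it is exposed for inspection only.
#'
#' @param measured,predicted Numeric vectors of equal length.
#' @param method `"residual"` or `"as_printed"`.
#' @return RMSE value (same units as the target).
#' @export
rmse <- function(measured, predicted, method = c("residual", "as_printed")) {
  method <- match.arg(method)
  if (length(measured) != length(predicted)) stop("length mismatch", call. = FALSE)
  if (!length(measured)) stop("need n >= 1", call. = FALSE)
  if (method == "residual") {
    sqrt(mean((measured - predicted)^2))
  } else {
    sqrt(mean((measured - mean(predicted))^2))
  }
}
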