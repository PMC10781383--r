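#' Induction-learner specification
#'
#' Describes the internal model that scores candidate variable subsets
#' during selection: partial least squares (`"pls"`), ordinary linear
#' regression (`"lm"`) or an RBF-kernel support vector machine
#' (`"svm_rbf"`), together with its hyperparameter grid and the repeated
#' k-fold evaluation settings.
#'
#' Tuning modes: `"grid"` (default) runs a single-level grid search that
#' shares the evaluation folds — the subset's score is the grid minimum of
#' the repeated k-fold RMSE, matching a grid search being used to determine
#' the learner parameters at each selection loop. `"nested"` tunes on an
#' inner 3-fold split of each training partition before predicting the held
#' out fold, avoiding tuning optimism at roughly triple the cost.
#'
#' @param kind `"pls"`, `"lm"` or `"svm_rbf"`.
#' @param grid Hyperparameter grid; defaults: PLS latent factors
#'   `1..min(15, p)`, SVM `cost` in \{0.1, 0.5, 1, 2, 5, 10\} crossed with
#'   `gamma` in \{0.005, 0.01, 0.05, 0.1, 0.5, 1\}, none for `lm`.
#' @param folds Cross-validation folds (>= 2).
#' @param repeats Repeats of the k-fold split.
#' @param tuning `"grid"` or `"nested"`.
#' @param seed Seed for the fold assignments.
#' @return A `learner_spec`.
#' @export
learner_spec <- function(kind = c("pls", "lm", "svm_rbf"), grid = NULL,
                         folds = 5, repeats = 5,
                         tuning = c("grid", "nested"), seed = 1) {
  kind <- match.arg(kind)
  tuning <- match.arg(tuning)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (is.null(grid)) {
    grid <- switch(kind,
      pls = data.frame(ncomp = 1:15),
      lm = data.frame(.none = 1),
      svm_rbf = expand.grid(cost = c(0.1, 0.5, 1, 2, 5, 10),
                            gamma = c(0.005, 0.01, 0.05, 0.1, 0.5, 1)))
  }
  if (!nrow(grid)) stop("hyperparameter grid is empty", call. = FALSE)
  structure(list(kind = kind, grid = grid, folds = folds, repeats = repeats,
                 tuning = tuning, seed = seed), class = "learner_spec")
}

.as_matrix_named <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) && is.null(colnames(x))) {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  x
}

# Fit one learner with fixed hyperparameters; returns a model with a
# $predict(newx) closure. SVR standardizes the target internally (eps = 0.1
# on the standardized scale); PLS centres only.
.fit_learner <- function(kind, x, y, params) {
  x <- .as_matrix_named(x)
  if (stats::sd(y) < 1e-12) {
    yc <- mean(y)
    return(list(kind = "const", predict = function(newx) rep(yc, nrow(newx))))
  }
  if (kind == "lm") {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x), y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    list(kind = "lm", coef = cf,
         predict = function(newx) {
           as.vector(cbind(1, .as_matrix_named(newx)) %*% cf)
         })
  } else if (kind == "svm_rbf") {
    ym <- mean(y); ys <- stats::sd(y)
    fit <- e1071::svm(x, (y - ym) / ys, type = "eps-regression",
                      kernel = "radial", cost = params$cost,
                      gamma = params$gamma, epsilon = 0.1, scale = FALSE)
    list(kind = "svm_rbf", fit = fit,
         predict = function(newx) {
           as.vector(stats::predict(fit, .as_matrix_named(newx))) * ys + ym
         })
  } else {  # pls
    if (ncol(x) == 1) {
      # one-component PLS on a single predictor is simple least squares
      b <- stats::cov(x[, 1], y) / stats::var(x[, 1])
      a <- mean(y) - b * mean(x[, 1])
      pr <- function(newx) a + b * .as_matrix_named(newx)[, 1]
      return(list(kind = "pls", ncomp = 1L, predict = pr,
                  predict_all = function(newx) cbind(pr(newx)),
                  coef = stats::setNames(b, colnames(x))))
    }
    ncomp <- min(params$ncomp, ncol(x), nrow(x) - 1)
    fit <- mixOmics::pls(x, y, ncomp = ncomp, mode = "regression",
                         scale = FALSE)
    list(kind = "pls", fit = fit, ncomp = ncomp,
         predict = function(newx) {
           newx <- .as_matrix_named(newx)[, colnames(x), drop = FALSE]
           stats::predict(fit, newx)$predict[, 1, ncomp]
         },
         predict_all = function(newx) {
           newx <- .as_matrix_named(newx)[, colnames(x), drop = FALSE]
           p <- stats::predict(fit, newx)$predict
           matrix(p[, 1, ], nrow = nrow(newx))
         })
  }
}

# Predictions of a single PLS fit for every component count up to its ncomp
# (one fit serves the whole latent-factor grid).
.pls_predict_all <- function(model, newx) {
  if (model$kind == "const") {
    return(cbind(model$predict(.as_matrix_named(newx))))
  }
  model$predict_all(newx)
}

.make_folds <- function(n, folds, repeats) {
  lapply(seq_len(repeats), function(r) sample(rep(seq_len(folds), length.out = n)))
}

#' Repeated k-fold cross-validated RMSE of a variable subset
#'
#' The evaluation function shared by all three selection algorithms: the
#' learner is tuned over its grid (see [learner_spec()] for the two tuning
#' modes), fitted per fold, and the held-out predictions are pooled into a
#' per-repeat RMSE which is averaged over repeats. Deterministic given the
#' learner's seed.
#'
#' @param x Feature matrix restricted to the candidate subset.
#' @param y Target vector.
#' @param learner A [learner_spec()].
#' @param keep_models Also return per-fold fitted models of the first
#'   repeat at the selected hyperparameters (used for permutation
#'   importance).
#' @return Numeric RMSE with attributes `best_params` (the selected grid
#'   row) and, if requested, `models` / `fold_id`.
#' @export
cv_rmse <- function(x, y, learner, keep_models = FALSE) {
  x <- .as_matrix_named(x)
  y <- as.vector(y)
  if (ncol(x) < 1) stop("empty variable subset", call. = FALSE)
  n <- nrow(x)
  if (n < learner$folds) stop("fewer samples than folds", call. = FALSE)
  withr::with_seed(learner$seed, {
    assign_list <- .make_folds(n, learner$folds, learner$repeats)
    if (learner$tuning == "grid") {
      res <- .cv_grid(x, y, learner, assign_list)
    } else {
      res <- .cv_nested(x, y, learner, assign_list)
    }
    out <- res$rmse
    attr(out, "best_params") <- res$best_params
    if (keep_models) {
      fold_id <- assign_list[[1]]
      models <- lapply(seq_len(learner$folds), function(f) {
        tr <- fold_id != f
        .fit_learner(learner$kind, x[tr, , drop = FALSE], y[tr],
                     res$best_params)
      })
      attr(out, "models") <- models
      attr(out, "fold_id") <- fold_id
    }
    out
  })
}

# Single-level grid search: pooled held-out RMSE per grid point, averaged
# over repeats; returns the grid minimum.
.cv_grid <- function(x, y, learner, assign_list) {
  grid <- learner$grid
  if (learner$kind == "pls") {
    tr_min <- nrow(x) -
      max(vapply(assign_list, function(a) max(tabulate(a, learner$folds)), 0L))
    ncomp_max <- min(max(grid$ncomp), ncol(x), tr_min - 1)
    ncomp_max <- max(1, ncomp_max)
    grid <- data.frame(ncomp = seq_len(ncomp_max))
  }
  ng <- nrow(grid)
  rep_rmse <- matrix(NA_real_, length(assign_list), ng)
  for (r in seq_along(assign_list)) {
    fold_id <- assign_list[[r]]
    pred <- matrix(NA_real_, length(y), ng)
    for (f in seq_len(learner$folds)) {
      te <- fold_id == f; tr <- !te
      if (stats::sd(y[tr]) < 1e-12) {
        warning("degenerate fold (constant training target); fold skipped",
                call. = FALSE)
        next
      }
      if (learner$kind == "pls") {
        m <- .fit_learner("pls", x[tr, , drop = FALSE], y[tr],
                          list(ncomp = max(grid$ncomp)))
        pm <- .pls_predict_all(m, x[te, , drop = FALSE])
        pred[te, seq_len(ncol(pm))] <- pm
        if (ncol(pm) < ng) pred[te, (ncol(pm) + 1):ng] <- pm[, ncol(pm)]
      } else {
        for (g in seq_len(ng)) {
          m <- .fit_learner(learner$kind, x[tr, , drop = FALSE], y[tr],
                            as.list(grid[g, , drop = FALSE]))
          pred[te, g] <- m$predict(x[te, , drop = FALSE])
        }
      }
    }
    rep_rmse[r, ] <- sqrt(colMeans((y - pred)^2, na.rm = TRUE))
  }
  mean_rmse <- colMeans(rep_rmse)
  best <- which.min(mean_rmse)
  list(rmse = mean_rmse[best],
       best_params = as.list(grid[best, , drop = FALSE]))
}

# Nested tuning: inner 3-fold grid search on each training partition.
.cv_nested <- function(x, y, learner, assign_list) {
  inner <- learner_spec(learner$kind, grid = learner$grid, folds = 3,
                        repeats = 1, tuning = "grid", seed = learner$seed + 1)
  chosen <- NULL
  rep_rmse <- rep(NA_real_, length(assign_list))
  for (r in seq_along(assign_list)) {
    fold_id <- assign_list[[r]]
    pred <- rep(NA_real_, length(y))
    for (f in seq_len(learner$folds)) {
      te <- fold_id == f; tr <- !te
      if (stats::sd(y[tr]) < 1e-12) {
        warning("degenerate fold (constant training target); fold skipped",
                call. = FALSE)
        next
      }
      sc <- cv_rmse(x[tr, , drop = FALSE], y[tr], inner)
      pars <- attr(sc, "best_params")
      m <- .fit_learner(learner$kind, x[tr, , drop = FALSE], y[tr], pars)
      pred[te] <- m$predict(x[te, , drop = FALSE])
      chosen <- pars
    }
    rep_rmse[r] <- sqrt(mean((y - pred)^2, na.rm = TRUE))
  }
  list(rmse = mean(rep_rmse), best_params = chosen)
}
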