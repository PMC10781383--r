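#' Variable-selection results
#'
#' All three selection algorithms return a `selection_result` holding the
#' ordered candidate sequence, the RMSE curve over evaluated steps, the
#' chosen subset and the evaluation metadata.
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @name selection_result
NULL

.selection_result <- function(algorithm, learner, target, order, curve,
                              curve_sizes, subset, chosen_step,
                              n_candidates) {
  structure(list(algorithm = algorithm, learner = learner$kind,
                 target = target, order = order,
                 n_candidates = n_candidates,
                 curve = curve, curve_sizes = curve_sizes,
                 subset = subset, chosen_step = chosen_step,
                 folds = learner$folds, repeats = learner$repeats,
                 tuning = learner$tuning, seed = learner$seed),
            class = "selection_result")
}

#' @rdname selection_result
#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("%s selection (%s learner, target %s): %d of %d variables\n",
              toupper(x$algorithm), x$learner, x$target,
              length(x$subset), x$n_candidates))
  cat("  subset:", paste(x$subset, collapse = " "), "\n")
  cat(sprintf("  RMSE at chosen step: %.4f (folds %d x repeats %d, seed %d)\n",
              x$curve[x$chosen_step], x$folds, x$repeats, x$seed))
  invisible(x)
}

#' @rdname selection_result
#' @export
plot.selection_result <- function(x, ...) {
  graphics::plot(x$curve_sizes, x$curve, type = "b", pch = 16,
                 xlab = "number of variables", ylab = "CV RMSE",
                 main = sprintf("%s / %s (%s)", toupper(x$algorithm),
                                x$learner, x$target), ...)
  graphics::points(x$curve_sizes[x$chosen_step], x$curve[x$chosen_step],
                   col = "red", cex = 2, lwd = 2)
  invisible(x)
}

#' @rdname selection_result
#' @param path JSON output path.
#' @export
write_selection_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.check_sel_input <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (!isTRUE(table$normalized)) {
    stop("selection requires a normalized feature table", call. = FALSE)
  }
}

#' Forward filtering selection by correlation order (CORR)
#'
#' Variables are ranked by descending absolute Pearson correlation with the
#' target and added one at a time in that order; the cross-validated RMSE
#' is evaluated at every prefix length until all variables have been
#' traversed. The chosen subset is the prefix at the curve minimum
#' (smallest prefix on ties).
#'
#' @param table A normalized `feature_table`.
#' @param target `"chl_ab"` or `"car"`.
#' @param learner A [learner_spec()].
#' @return A `selection_result` with a full-length RMSE curve.
#' @export
corr_select <- function(table, target = c("chl_ab", "car"), learner) {
  .check_sel_input(table)
  target <- match.arg(target)
  ord <- rank_by_correlation(table, target)$variable
  y <- table$targets[[target]]
  curve <- vapply(seq_along(ord), function(k) {
    as.numeric(cv_rmse(table$features[, ord[seq_len(k)], drop = FALSE],
                       y, learner))
  }, 0)
  k_star <- which.min(curve)  # which.min returns the smallest index on ties
  .selection_result("corr", learner, target, ord, curve,
                    seq_along(ord), ord[seq_len(k_star)], k_star,
                    length(ord))
}

#' Sequential forward selection (SFS)
#'
#' Starts from the empty subset; at each iteration every not-yet-included
#' variable is evaluated added to the current subset and the best is
#' accepted. Iteration stops when the best candidate no longer improves on
#' the previous best merit, or when `max_vars` is reached, so the
#' accepted-step RMSE sequence is strictly decreasing. The per-iteration
#' resampling is re-seeded deterministically from the learner seed.
#'
#' @inheritParams corr_select
#' @param max_vars Maximum subset size.
#' @return A `selection_result`; the curve holds the accepted-step RMSEs.
#' @export
sfs_select <- function(table, target = c("chl_ab", "car"), learner,
                       max_vars = ncol(table$features)) {
  .check_sel_input(table)
  target <- match.arg(target)
  y <- table$targets[[target]]
  vars <- colnames(table$features)
  subset <- character(0)
  curve <- numeric(0)
  best_prev <- Inf
  iter <- 0
  while (length(subset) < max_vars) {
    iter <- iter + 1
    it_learner <- learner
    it_learner$seed <- learner$seed + iter
    cand <- setdiff(vars, subset)
    if (!length(cand)) break
    scores <- vapply(cand, function(v) {
      as.numeric(cv_rmse(table$features[, c(subset, v), drop = FALSE],
                         y, it_learner))
    }, 0)
    best <- which.min(scores)
    # improvement below numerical noise does not count as better merit
    if (is.finite(best_prev) &&
        scores[best] >= best_prev - 1e-10 * max(1, best_prev)) break
    subset <- c(subset, cand[best])
    curve <- c(curve, scores[best])
    best_prev <- scores[best]
  }
  if (!length(subset)) stop("SFS accepted no variable", call. = FALSE)
  .selection_result("sfs", learner, target, subset, curve,
                    seq_along(subset), subset, length(subset),
                    length(vars))
}

# Variable importances for the RFE ranking. Linear learners use the
# magnitude of the (standardized-input) coefficients; the RBF-SVM has no
# native weights, so seeded permutation importance over the CV fold models
# is used: each variable is permuted n_perm times within the held-out parts
# and the importance is the mean pooled-CV-RMSE increase.
.rfe_importance <- function(x, y, learner, score, n_perm = 10) {
  if (learner$kind == "lm") {
    m <- .fit_learner("lm", x, y, list())
    abs(m$coef[-1])
  } else if (learner$kind == "pls") {
    pars <- attr(score, "best_params")
    m <- .fit_learner("pls", x, y, pars)
    bh <- stats::predict(m$fit, x)$B.hat
    imp <- abs(bh[, 1, dim(bh)[3]])
    imp[colnames(x)]
  } else {
    models <- attr(score, "models")
    fold_id <- attr(score, "fold_id")
    base_pred <- rep(NA_real_, nrow(x))
    for (f in seq_along(models)) {
      te <- fold_id == f
      base_pred[te] <- models[[f]]$predict(x[te, , drop = FALSE])
    }
    base <- sqrt(mean((y - base_pred)^2))
    withr::with_seed(learner$seed + 7919 + ncol(x), {
      imp <- vapply(seq_len(ncol(x)), function(j) {
        inc <- vapply(seq_len(n_perm), function(p) {
          pred <- rep(NA_real_, nrow(x))
          for (f in seq_along(models)) {
            te <- fold_id == f
            xp <- x[te, , drop = FALSE]
            xp[, j] <- xp[sample(nrow(xp)), j]
            pred[te] <- models[[f]]$predict(xp)
          }
          sqrt(mean((y - pred)^2)) - base
        }, 0)
        mean(inc)
      }, 0)
      names(imp) <- colnames(x)
      imp
    })
  }
}

#' Recursive feature elimination (RFE)
#'
#' Starts with all variables; at each loop the learner is fitted and
#' cross-validated on the current set, the variables are ranked by learner
#' importance, and the least important is eliminated, down to a single
#' variable. The chosen subset is the recorded set with minimal CV RMSE.
#'
#' @inheritParams corr_select
#' @return A `selection_result` whose curve has one entry per elimination
#'   step (sizes p, p-1, .., 1).
#' @export
rfe_select <- function(table, target = c("chl_ab", "car"), learner) {
  .check_sel_input(table)
  target <- match.arg(target)
  y <- table$targets[[target]]
  current <- colnames(table$features)
  p <- length(current)
  curve <- numeric(p)
  sizes <- integer(p)
  sets <- vector("list", p)
  eliminated <- character(0)
  for (step in seq_len(p)) {
    x <- table$features[, current, drop = FALSE]
    score <- cv_rmse(x, y, learner, keep_models = learner$kind == "svm_rbf")
    curve[step] <- as.numeric(score)
    sizes[step] <- length(current)
    sets[[step]] <- current
    if (length(current) == 1) break
    imp <- .rfe_importance(x, y, learner, score)
    worst <- names(imp)[which.min(imp)]
    eliminated <- c(eliminated, worst)
    current <- setdiff(current, worst)
  }
  best <- which.min(curve)
  .selection_result("rfe", learner, target,
                    c(eliminated, current), curve, sizes,
                    sets[[best]], best, p)
}
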