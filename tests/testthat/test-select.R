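# A toy problem where the target depends on the two variables most
# correlated with it, plus distractors.
toy_problem <- function(n = 40, p = 6, seed = 41, noise = 0.05) {
  d <- toy_regression(n, p, seed, noise)
  toy_feature_table(d$x, chl_ab = d$y)
}

test_that("CORR evaluates the full prefix curve and picks its minimum", {
  ft <- toy_problem()
  sel <- corr_select(ft, "chl_ab", learner_spec("lm", repeats = 2, seed = 3))
  expect_equal(length(sel$curve), 6)
  expect_equal(sel$curve_sizes, 1:6)
  expect_lte(sel$curve[sel$chosen_step], sel$curve[6])
  expect_equal(sel$subset, sel$order[seq_len(sel$chosen_step)])
  expect_true(sel$chosen_step %in% 2:3)  # target is built from the top-2
  # curve equals exhaustive prefix-wise recomputation
  ls <- learner_spec("lm", repeats = 2, seed = 3)
  manual <- vapply(1:6, function(k) {
    as.numeric(cv_rmse(ft$features[, sel$order[1:k], drop = FALSE],
                       ft$targets$chl_ab, ls))
  }, 0)
  expect_equal(sel$curve, manual, tolerance = 1e-12)
})

test_that("CORR with one candidate returns a one-point curve", {
  ft <- toy_problem(p = 1)
  sel <- corr_select(ft, "chl_ab", learner_spec("lm", repeats = 2, seed = 3))
  expect_equal(length(sel$curve), 1)
  expect_equal(sel$subset, "x1")
})

test_that("SFS stops after an exactly sufficient variable", {
  withr::with_seed(44, {
    x <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("x", 1:4)))
  })
  ft <- toy_feature_table(x, chl_ab = x[, 3])
  sel <- sfs_select(ft, "chl_ab", learner_spec("lm", repeats = 2, seed = 5))
  expect_equal(sel$subset, "x3")
  expect_equal(length(sel$curve), 1)
})

test_that("SFS accepted-step RMSEs strictly decrease and match brute force", {
  ft <- toy_problem(noise = 0.3)
  ls <- learner_spec("lm", repeats = 2, seed = 7)
  sel <- sfs_select(ft, "chl_ab", ls)
  expect_true(all(diff(sel$curve) < 0))
  # independent greedy re-run with the same per-iteration re-seeding protocol
  subset <- character(0); best_prev <- Inf
  repeat {
    it <- ls; it$seed <- ls$seed + length(subset) + 1
    cand <- setdiff(colnames(ft$features), subset)
    sc <- vapply(cand, function(v) {
      as.numeric(cv_rmse(ft$features[, c(subset, v), drop = FALSE],
                         ft$targets$chl_ab, it))
    }, 0)
    b <- which.min(sc)
    if (is.finite(best_prev) && sc[b] >= best_prev - 1e-10 * max(1, best_prev)) break
    subset <- c(subset, cand[b]); best_prev <- sc[b]
  }
  expect_equal(sel$subset, subset)
})

test_that("RFE keeps a truly predictive variable and records a full curve", {
  ft <- toy_problem(p = 5, noise = 0.05)
  sel <- rfe_select(ft, "chl_ab", learner_spec("lm", repeats = 2, seed = 9))
  expect_equal(length(sel$curve), 5)
  expect_equal(sel$curve_sizes, 5:1)
  expect_true("x1" %in% sel$subset)
  expect_equal(sel$order[5], "x1")  # strongest variable survives to the end
  expect_equal(sel$curve[sel$chosen_step], min(sel$curve))
})

test_that("RFE's lm elimination order matches refitted coefficient ranking", {
  ft <- toy_problem(p = 5, noise = 0.2, seed = 47)
  ls <- learner_spec("lm", repeats = 2, seed = 11)
  sel <- rfe_select(ft, "chl_ab", ls)
  current <- colnames(ft$features)
  manual_order <- character(0)
  while (length(current) > 1) {
    fit <- lm(ft$targets$chl_ab ~ ft$features[, current, drop = FALSE])
    co <- abs(coef(fit)[-1]); names(co) <- current
    worst <- names(co)[which.min(co)]
    manual_order <- c(manual_order, worst)
    current <- setdiff(current, worst)
  }
  expect_equal(sel$order, c(manual_order, current))
})

test_that("RFE permutation importance protects the informative variable (svm)", {
  ft <- toy_problem(n = 50, p = 4, noise = 0.1, seed = 48)
  ls <- learner_spec("svm_rbf", grid = expand.grid(cost = c(1, 10), gamma = 0.25),
                     repeats = 1, seed = 13)
  sel <- rfe_select(ft, "chl_ab", ls)
  expect_equal(length(sel$curve), 4)
  expect_true("x1" %in% sel$subset)
})

test_that("selection results are deterministic and serializable", {
  ft <- toy_problem()
  ls <- learner_spec("lm", repeats = 2, seed = 17)
  s1 <- sfs_select(ft, "chl_ab", ls)
  s2 <- sfs_select(ft, "chl_ab", ls)
  expect_identical(s1$subset, s2$subset)
  expect_identical(s1$curve, s2$curve)
  expect_true(all(s1$subset %in% colnames(ft$features)))
  p <- withr::local_tempfile(fileext = ".json")
  write_selection_json(s1, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$subset, s1$subset)
  expect_error(sfs_select(toy_problem()["features"], "chl_ab", ls))
})

test_that("selection requires a normalized table", {
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("x", 1:3)))
  raw <- structure(list(features = x,
                        targets = data.frame(chl_ab = rnorm(20), car = rnorm(20)),
                        mode = "as_printed", normalized = FALSE,
                        center = NULL, scale = NULL),
                   class = "feature_table")
  expect_error(corr_select(raw, "chl_ab", learner_spec("lm")), "normalized")
})
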