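# Stratified folds, held-out deviance per grid cell, and complexity
# selection with the parsimony tie-break and representative repeat.

test_that("stratified folds balance classes to within one", {
  y <- rep(c(1, 0), c(100, 900))
  f <- stratified_folds(y, 10, seed = 1)
  expect_identical(as.integer(table(f[y == 1])), rep(10L, 10))
  expect_identical(as.integer(table(f[y == 0])), rep(90L, 10))

  y2 <- rep(c(1, 0), c(101, 899))
  f2 <- stratified_folds(y2, 10, seed = 2)
  expect_true(all(table(f2[y2 == 1]) %in% c(10L, 11L)))

  expect_identical(stratified_folds(y, 10, seed = 7),
                   stratified_folds(y, 10, seed = 7))
  expect_false(identical(stratified_folds(y, 10, seed = 7),
                         stratified_folds(y, 10, seed = 8)))
})

test_that("held-out deviance is near zero when the outcome saturates", {
  set.seed(241)
  X <- matrix(rbinom(400 * 5, 1, 0.5), 400, 5)
  y <- X[, 1]
  folds <- stratified_folds(y, 4, seed = 3)
  cell <- cv_cell_deviance(X, y, 1, 1, folds,
                           schedule = anneal_schedule(end = 0.5, n_iter = 300),
                           seed = 5)
  # oracle: scoring the true rule itself out of sample gives ~0 deviance
  expect_lt(cell$mean, 0.01)
  expect_equal(nrow(cell$per_fold), 4)
})

test_that("cv cell matches the enumerated best single predictor", {
  set.seed(251)
  X <- matrix(rbinom(600 * 5, 1, 0.5), 600, 5)
  y <- rbinom(600, 1, plogis(-1 + 1.6 * X[, 2]))
  folds <- stratified_folds(y, 3, seed = 11)
  cell <- cv_cell_deviance(X, y, 1, 1, folds,
                           schedule = anneal_schedule(end = 0.5, n_iter = 500),
                           seed = 13, restarts = 2)
  # oracle: exhaustive scan over single-leaf trees per fold
  oracle <- numeric(3)
  for (k in 1:3) {
    test <- folds == k
    ex <- exhaustive_search(X[!test, , drop = FALSE], y[!test], max_leaves = 1)
    m <- fit_logic_model(list(ex$tree), X[!test, , drop = FALSE], y[!test])
    oracle[k] <- score_model(m, X[test, , drop = FALSE], y[test],
                             normalize = TRUE)
  }
  expect_equal(cell$mean, mean(oracle), tolerance = 0.02)
})

test_that("single-class folds are flagged and the cell skipped", {
  X <- matrix(rbinom(40, 1, 0.5), 20, 2)
  y <- c(1, rep(0, 19))
  folds <- rep(1:2, each = 10)  # fold 2 has no events
  expect_warning(
    cell <- cv_cell_deviance(X, y, 1, 1, folds,
                             schedule = anneal_schedule(end = 0.5,
                                                        n_iter = 50)),
    "single outcome class")
  expect_true(is.na(cell$mean))
})

test_that("selection takes the grand-mean argmin with parsimony tie-break", {
  # synthetic grid results with a unique minimum at (2 trees, 3 leaves)
  cells <- expand.grid(repeat_ = 1:3, p_trees = 1:3, leaf_budget = 1:4,
                       fold = 1)
  cells$test_deviance <- 1.0
  cells$test_deviance[cells$p_trees == 2 & cells$leaf_budget == 3] <-
    c(0.80, 0.90, 0.70)  # repeat means; grand mean 0.80
  sel <- select_model(structure(cells, class = c("cv_grid", "data.frame")))
  expect_equal(sel$selected$p_trees, 2)
  expect_equal(sel$selected$leaf_budget, 3)
  # repeat 1 (mean 0.80) is closest to the grand mean 0.80
  expect_equal(sel$representative_repeat, 1)

  # exact tie between (1,4) and (2,4): fewer total leaves wins
  cells2 <- expand.grid(repeat_ = 1:2, p_trees = 1:2, leaf_budget = 4,
                        fold = 1)
  cells2$test_deviance <- 0.5
  sel2 <- select_model(structure(cells2, class = c("cv_grid", "data.frame")))
  expect_equal(sel2$selected$p_trees, 1)
  expect_equal(sel2$selected$leaf_budget, 4)
})

test_that("the cv grid is reproducible under its master seed", {
  set.seed(261)
  X <- matrix(rbinom(200 * 4, 1, 0.5), 200, 4)
  y <- rbinom(200, 1, plogis(X[, 1] - 0.5))
  g1 <- cv_grid(X, y, tree_grid = 1, leaf_grid = 1:2, k = 3, n_repeats = 2,
                schedule = anneal_schedule(end = 0.5, n_iter = 100), seed = 17)
  g2 <- cv_grid(X, y, tree_grid = 1, leaf_grid = 1:2, k = 3, n_repeats = 2,
                schedule = anneal_schedule(end = 0.5, n_iter = 100), seed = 17)
  expect_identical(g1$test_deviance, g2$test_deviance)
  expect_equal(nrow(g1), 2 * 2 * 3)  # repeats x cells x folds
})
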