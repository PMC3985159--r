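# Model-complexity selection by repeated, stratified ten-fold
# cross-validation on held-out binomial deviance.  The grid spans the number
# of trees and the leaf budget; the cell with the smallest deviance averaged
# over folds and repeats is selected, and the "representative" repeat — the
# one whose cell mean is closest to the grand mean — is identified so a
# typical rather than extreme data split is reported.

#' Stratified fold assignment
#'
#' Randomly partitions observations into `k` folds such that each fold
#' contains one k-th of each outcome class (per-class fold counts differ by
#' at most 1).
#'
#' @param y 0/1 outcome vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold assignment in `1..k`, one per observation.
#' @export
stratified_folds <- function(y, k = 10L, seed = NULL) {
  y <- as.integer(y != 0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx[sample.int(length(idx))]] <-
      rep_len(sample.int(k), length(idx))
  }
  folds
}

#' Mean held-out deviance for one complexity cell
#'
#' For each fold, a logic model is fit by simulated annealing on the other
#' folds and its binomial deviance is evaluated on the held-out fold with
#' coefficients fixed; the per-observation held-out deviances are averaged
#' over folds (normalising by fold size so unequal folds weigh fairly).
#' A fold whose training or test part contains a single outcome class is
#' flagged and the cell is skipped (`NA`).
#'
#' @param X 0/1 predictor matrix or `binary_design`.
#' @param y 0/1 outcome vector.
#' @param p_trees,leaf_budget model complexity of the cell.
#' @param folds fold assignment from [stratified_folds()].
#' @param schedule an [anneal_schedule()].
#' @param seed integer seed for the annealing runs.
#' @param restarts annealing restarts per fold.
#' @return list with `mean` (mean per-observation held-out deviance) and
#'   `per_fold` (data frame fold/test_deviance/n_test).
#' @export
cv_cell_deviance <- function(X, y, p_trees, leaf_budget, folds,
                             schedule = anneal_schedule(), seed = NULL,
                             restarts = 1L) {
  if (inherits(X, "binary_design") && is.null(y)) y <- X$y
  Xm <- design_matrix(X)
  y <- as.integer(y != 0)
  ks <- sort(unique(folds))
  per <- data.frame(fold = ks, test_deviance = NA_real_,
                    n_test = NA_integer_)
  for (i in seq_along(ks)) {
    test <- folds == ks[i]
    if (length(unique(y[!test])) < 2L || length(unique(y[test])) < 2L) {
      warning("fold ", ks[i], " has a single outcome class; cell skipped")
      return(list(mean = NA_real_, per_fold = per))
    }
    m <- anneal_fit(Xm[!test, , drop = FALSE], y[!test], p_trees, leaf_budget,
                    schedule = schedule,
                    seed = if (is.null(seed)) NULL else seed + i,
                    restarts = restarts)
    per$test_deviance[i] <- score_model(m, Xm[test, , drop = FALSE], y[test],
                                        normalize = TRUE)
    per$n_test[i] <- sum(test)
  }
  list(mean = mean(per$test_deviance), per_fold = per)
}

#' Repeated cross-validation over a complexity grid
#'
#' Runs `n_repeats` rounds of stratified `k`-fold cross-validation, each
#' with a fresh random split, over all (number of trees, leaf budget) cells.
#'
#' @param X 0/1 predictor matrix or `binary_design`.
#' @param y 0/1 outcome vector.
#' @param tree_grid numbers of trees to try (default 1:4).
#' @param leaf_grid leaf budgets to try (default 1:15).
#' @param k folds (default 10).
#' @param n_repeats cross-validation rounds (default 15).
#' @param schedule an [anneal_schedule()].
#' @param seed master seed; fold splits and annealing seeds derive from it,
#'   so the full grid is reproducible.
#' @param restarts annealing restarts per fold.
#' @return a `cv_grid` object: long data frame (`repeat_`, `p_trees`,
#'   `leaf_budget`, `fold`, `test_deviance`, `n_test`) with class attributes
#'   used by [select_model()].
#' @export
cv_grid <- function(X, y = NULL, tree_grid = 1:4, leaf_grid = 1:15,
                    k = 10L, n_repeats = 15L,
                    schedule = anneal_schedule(), seed = 1L, restarts = 1L) {
  if (inherits(X, "binary_design") && is.null(y)) y <- X$y
  Xm <- design_matrix(X)
  y <- as.integer(y != 0)
  rows <- list()
  for (rep_i in seq_len(n_repeats)) {
    folds <- stratified_folds(y, k, seed = seed + 1000L * rep_i)
    for (p in tree_grid) for (b in leaf_grid) {
      cell <- cv_cell_deviance(Xm, y, p, b, folds, schedule = schedule,
                               seed = seed + 1000L * rep_i + 37L * p + b,
                               restarts = restarts)
      pf <- cell$per_fold
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_ = rep_i, p_trees = p, leaf_budget = b,
                   fold = pf$fold, test_deviance = pf$test_deviance,
                   n_test = pf$n_test)
    }
  }
  structure(do.call(rbind, rows), class = c("cv_grid", "data.frame"))
}

#' Summarise a CV grid: repeat-level and grand means
#'
#' @param grid a `cv_grid` (or equivalent long data frame).
#' @return list with `repeat_means` (repeat x cell data frame) and
#'   `grand_means` (cell data frame, arithmetic mean over repeats).
#' @export
cv_summaries <- function(grid) {
  repeat_means <- stats::aggregate(
    test_deviance ~ repeat_ + p_trees + leaf_budget, data = grid,
    FUN = mean, na.action = stats::na.pass)
  grand_means <- stats::aggregate(
    test_deviance ~ p_trees + leaf_budget, data = repeat_means, FUN = mean,
    na.action = stats::na.pass)
  list(repeat_means = repeat_means, grand_means = grand_means)
}

#' Select model complexity from repeated-CV results
#'
#' The cell with the smallest deviance averaged over repeats is selected;
#' exact ties break towards parsimony (smaller total leaves
#' `p_trees * leaf_budget`, then fewer trees).  The representative repeat is
#' the one whose mean at the selected cell is closest to the grand mean.
#' When data are supplied the final model is refit by annealing on the full
#' data at the selected complexity.
#'
#' @param grid a `cv_grid` from [cv_grid()].
#' @param X,y optional data for the final full-data refit.
#' @param schedule,seed,restarts annealing settings for the refit.
#' @return a `cv_selection`: `selected` (p_trees, leaf_budget, grand mean),
#'   `representative_repeat`, `grand_means`, `repeat_means`, and `model`
#'   (the full-data refit, or `NULL`).
#' @export
select_model <- function(grid, X = NULL, y = NULL,
                         schedule = anneal_schedule(), seed = 1L,
                         restarts = 10L) {
  s <- cv_summaries(grid)
  gm <- s$grand_means[!is.na(s$grand_means$test_deviance), , drop = FALSE]
  if (!nrow(gm)) stop("no feasible cells in the CV grid")
  ord <- order(gm$test_deviance,
               gm$p_trees * gm$leaf_budget,  # parsimony: fewer total leaves
               gm$p_trees)                   # then fewer trees
  sel <- gm[ord[1L], ]

  rm <- s$repeat_means
  rm_sel <- rm[rm$p_trees == sel$p_trees & rm$leaf_budget == sel$leaf_budget, ]
  rep_idx <- rm_sel$repeat_[which.min(abs(rm_sel$test_deviance -
                                            sel$test_deviance))]

  model <- NULL
  if (!is.null(X)) {
    if (inherits(X, "binary_design") && is.null(y)) y <- X$y
    model <- anneal_fit(design_matrix(X), y, sel$p_trees, sel$leaf_budget,
                        schedule = schedule, seed = seed, restarts = restarts)
  }
  structure(list(selected = sel, representative_repeat = rep_idx,
                 grand_means = s$grand_means, repeat_means = s$repeat_means,
                 model = model),
            class = "cv_selection")
}

#' @export
print.cv_selection <- function(x, ...) {
  cat("Cross-validated complexity selection\n")
  cat("  selected: ", x$selected$p_trees, " tree(s), leaf budget ",
      x$selected$leaf_budget, " (mean held-out deviance/obs ",
      format(x$selected$test_deviance, digits = 5), ")\n", sep = "")
  cat("  representative repeat: ", x$representative_repeat, "\n", sep = "")
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}

#' Write CV grid results as long-format CSV
#'
#' @param grid a `cv_grid`.
#' @param path CSV path.
#' @export
write_cv_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}
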