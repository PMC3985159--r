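# Simulated-annealing search over logic-tree space, refitting the logistic
# coefficients at every proposal so trees and coefficients are estimated
# simultaneously; binomial deviance is the score being minimised.

#' Annealing schedule
#'
#' Geometric cooling from `start` to `end` over `n_iter` iterations.  When
#' `start` is `NULL` it is auto-tuned at run time from a burn-in probe of
#' random moves so that the initial acceptance rate of score-worsening moves
#' is roughly 0.9.
#'
#' @param start starting temperature (> `end`), or `NULL` to auto-tune.
#' @param end final temperature (> 0).
#' @param n_iter number of annealing iterations.
#' @param probe number of burn-in proposals used for auto-tuning.
#' @return an `anneal_schedule` object.
#' @export
anneal_schedule <- function(start = NULL, end = 1e-3, n_iter = 50000L,
                            probe = 500L) {
  stopifnot(end > 0, n_iter >= 1)
  if (!is.null(start) && start <= end)
    stop("schedule invalid: start temperature must exceed end temperature")
  structure(list(start = start, end = end, n_iter = as.integer(n_iter),
                 probe = as.integer(probe)),
            class = "anneal_schedule")
}

#' Metropolis acceptance probability
#'
#' A proposal with a better (lower) or equal score is always accepted;
#' otherwise it is accepted with probability `exp(-delta / temperature)`,
#' decaying with the score gap and the cooling temperature.
#'
#' @param delta_score proposed score minus current score.
#' @param temperature positive temperature.
#' @return acceptance probability in (0, 1].
#' @export
acceptance_prob <- function(delta_score, temperature) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  ifelse(delta_score <= 0, 1, exp(-delta_score / temperature))
}

#' Fit a logic-regression model by simulated annealing
#'
#' Searches over models with exactly `p_trees` Boolean trees, each limited to
#' `leaf_budget` leaves (or the model limited to `leaf_budget` leaves in
#' total when `budget_mode = "total"`).  At each step one tree is chosen
#' uniformly at random and a random applicable move (alternating a leaf or
#' operator, growing/pruning a branch, splitting/deleting a leaf) is
#' proposed; all coefficients are refit by IRLS and the proposal is accepted
#' by the Metropolis rule under geometric cooling.  The best-scoring model
#' visited is returned (best over all restarts).
#'
#' @param X n x k 0/1 predictor matrix (or `binary_design`).
#' @param y 0/1 outcome vector (taken from the design if omitted and bound).
#' @param p_trees number of trees, 1..4.
#' @param leaf_budget maximum leaves (per tree by default).
#' @param schedule an [anneal_schedule()].
#' @param seed integer seed making the search deterministic.
#' @param restarts independent restarts; best result kept.
#' @param budget_mode `"per_tree"` (default) or `"total"`.
#' @param trace if `TRUE`, attach a per-iteration trace (iteration,
#'   temperature, score, accepted, total leaves) as attribute `"trace"`.
#' @return a `logic_model`: intercept, list of trees with coefficients and
#'   standard errors, and the fitted binomial deviance.
#' @examples
#' set.seed(7)
#' X <- matrix(rbinom(500 * 4, 1, 0.5), 500, 4)
#' y <- X[, 1]  # outcome determined by predictor 1
#' m <- anneal_fit(X, y, p_trees = 1, leaf_budget = 2,
#'                 schedule = anneal_schedule(n_iter = 500), seed = 1)
#' render_tree(m$trees[[1]])
#' @export
anneal_fit <- function(X, y = NULL, p_trees, leaf_budget,
                       schedule = anneal_schedule(), seed = NULL,
                       restarts = 1L, budget_mode = c("per_tree", "total"),
                       trace = FALSE) {
  budget_mode <- match.arg(budget_mode)
  if (inherits(X, "binary_design") && is.null(y)) y <- X$y
  Xm <- design_matrix(X)
  if (is.null(dim(Xm)) || nrow(Xm) == 0L || ncol(Xm) == 0L)
    stop("empty design")
  stopifnot(p_trees >= 1, p_trees <= 4, leaf_budget >= 1)
  if (budget_mode == "total" && leaf_budget < p_trees)
    stop("total leaf budget smaller than the number of trees")
  if (!inherits(schedule, "anneal_schedule")) stop("schedule invalid")
  y <- as.integer(y != 0)
  stopifnot(length(y) == nrow(Xm))
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (r in seq_len(restarts)) {
    res <- anneal_once(Xm, y, p_trees, leaf_budget, schedule, budget_mode,
                       trace && r == 1L)
    if (is.null(best) || res$fit$deviance < best$fit$deviance) best <- res
  }
  model <- new_logic_model(best$trees, best$fit, nrow(Xm),
                           colnames(Xm))
  if (trace) attr(model, "trace") <- best$trace
  model
}

tree_columns <- function(trees, Xm) {
  vapply(trees, function(t) eval_tree_columns(t, Xm), integer(nrow(Xm)))
}

anneal_once <- function(Xm, y, p_trees, leaf_budget, schedule, budget_mode,
                        keep_trace) {
  k <- ncol(Xm)
  n <- nrow(Xm)

  # precomputed leaf columns (plain in slots 1..k, complemented in k+1..2k)
  # make tree evaluation in the hot loop a pure lookup-and-combine
  B <- Xm != 0
  Lmat <- cbind(B, !B)
  eval_fast <- function(node) {
    if (is_leaf(node))
      return(Lmat[, if (node$neg) k + node$leaf else node$leaf])
    if (node$op == "and") eval_fast(node$left) & eval_fast(node$right)
    else eval_fast(node$left) | eval_fast(node$right)
  }

  trees <- replicate(p_trees, random_tree(1L, k), simplify = FALSE)
  cols <- vapply(trees, eval_fast, logical(n))
  # single-tree chains score through the closed-form 2x2 fit directly
  score_cols <- if (p_trees == 1L) {
    function(cc) {
      v <- cc[, 1L]
      if (all(v == v[1L])) {
        f <- irls_collapsed(matrix(integer(0), length(y), 0L), y)
        list(coefficients = c(f$beta, NA_real_), se = c(f$se, NA_real_),
             deviance = f$deviance, converged = TRUE, dropped = 1L,
             separation = f$separation)
      } else {
        f <- fit_2x2(v, y)
        list(coefficients = f$beta, se = f$se, deviance = f$deviance,
             converged = TRUE, dropped = integer(0),
             separation = f$separation)
      }
    }
  } else {
    function(cc) fit_coefficients(cc, y, warn = FALSE)
  }
  fit <- score_cols(cols)

  max_leaves_for <- function(j) {
    if (budget_mode == "per_tree") leaf_budget
    else leaf_budget - sum(vapply(trees[-j], leaf_count, integer(1)))
  }
  propose <- function() {
    j <- if (p_trees > 1L) sample.int(p_trees, 1L) else 1L
    mv <- propose_move(trees[[j]], k, max_leaves_for(j))
    list(j = j, tree = apply_move(trees[[j]], mv))
  }

  # Auto-tune the start temperature from a burn-in random walk: every
  # proposal is taken, and the positive score gaps seen along the walk set
  # the scale at which ~90% of worsening moves are initially accepted.
  # Probing a walk (not just the initial state) is what exposes the gaps
  # between competing local modes.
  t_start <- schedule$start
  if (is.null(t_start)) {
    dpos <- numeric(0)
    w_trees <- trees; w_cols <- cols; w_fit <- fit
    for (i in seq_len(schedule$probe)) {
      j <- if (p_trees > 1L) sample.int(p_trees, 1L) else 1L
      mv <- propose_move(w_trees[[j]], k, if (budget_mode == "per_tree")
        leaf_budget else leaf_budget - sum(vapply(w_trees[-j], leaf_count,
                                                  integer(1))))
      new_tree <- apply_move(w_trees[[j]], mv)
      cols2 <- w_cols; cols2[, j] <- eval_fast(new_tree)
      fit2 <- score_cols(cols2)
      d <- fit2$deviance - w_fit$deviance
      if (d > 0) dpos <- c(dpos, d)
      w_trees[[j]] <- new_tree; w_cols <- cols2; w_fit <- fit2
    }
    t_start <- if (length(dpos)) {
      max(stats::quantile(dpos, 0.9) / -log(0.9), schedule$end * 10)
    } else 1
  }
  cool <- (schedule$end / t_start)^(1 / max(schedule$n_iter - 1L, 1L))

  best_trees <- trees; best_fit <- fit
  tr <- if (keep_trace)
    data.frame(iteration = seq_len(schedule$n_iter), temperature = NA_real_,
               score = NA_real_, accepted = NA, total_leaves = NA_integer_)
  else NULL

  temp <- t_start
  for (it in seq_len(schedule$n_iter)) {
    pr <- propose()
    cols2 <- cols; cols2[, pr$j] <- eval_fast(pr$tree)
    fit2 <- score_cols(cols2)
    delta <- fit2$deviance - fit$deviance
    acc <- delta <= 0 || stats::runif(1) < exp(-delta / temp)
    if (acc) {
      trees[[pr$j]] <- pr$tree
      cols <- cols2
      fit <- fit2
      if (fit$deviance < best_fit$deviance) {
        best_fit <- fit
        best_trees <- trees
      }
    }
    if (keep_trace) {
      tr$temperature[it] <- temp
      tr$score[it] <- fit$deviance
      tr$accepted[it] <- acc
      tr$total_leaves[it] <- sum(vapply(trees, leaf_count, integer(1)))
    }
    temp <- temp * cool
  }
  list(trees = best_trees, fit = best_fit, trace = tr)
}

new_logic_model <- function(trees, fit, n, predictor_names = NULL) {
  p <- length(trees)
  structure(list(
    intercept = fit$coefficients[1],
    coefficients = if (p) fit$coefficients[-1] else numeric(0),
    se = fit$se,
    trees = trees,
    deviance = fit$deviance,
    n = n,
    predictor_names = predictor_names,
    separation = isTRUE(fit$separation),
    dropped = fit$dropped),
    class = "logic_model")
}

#' Fit a logic model with fixed, user-supplied trees
#'
#' Refits only the logistic coefficients for a given list of trees (no
#' search); useful for scoring a known rule or refitting on new data.
#'
#' @param trees list of `logic_tree` objects.
#' @param X 0/1 predictor matrix or `binary_design`.
#' @param y 0/1 outcome vector.
#' @return a `logic_model`.
#' @export
fit_logic_model <- function(trees, X, y = NULL) {
  if (inherits(X, "binary_design") && is.null(y)) y <- X$y
  Xm <- design_matrix(X)
  new_logic_model(trees, fit_coefficients(tree_columns(trees, Xm), y, warn = FALSE),
                  nrow(Xm), colnames(Xm))
}

#' Recovered Boolean rule of a fitted tree, oriented by coefficient sign
#'
#' A tree with a negative coefficient is the complement of the
#' positively-oriented rule (same model, sign flipped), so rule-recovery
#' comparisons orient each fitted tree by its coefficient before testing
#' Boolean equivalence against a planted truth.
#'
#' @param model a `logic_model`.
#' @param j tree index.
#' @return a `logic_tree`: the tree itself if its coefficient is
#'   nonnegative, otherwise its [complement_tree()].
#' @export
recovered_rule <- function(model, j = 1L) {
  b <- model$coefficients[j]
  t <- model$trees[[j]]
  if (!is.na(b) && b < 0) complement_tree(t) else t
}

#' Predicted event probabilities from a logic model
#'
#' Forward direction of the logistic link:
#' \eqn{\mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j L_j(\mathrm{row}))}.
#' Trees whose coefficient was dropped from the fit contribute 0.
#'
#' @param model a `logic_model`.
#' @param X 0/1 predictor matrix or `binary_design`.
#' @return probability vector in (0, 1), one per row.
#' @export
predict_prob <- function(model, X) {
  Xm <- design_matrix(X)
  eta <- rep(model$intercept, nrow(Xm))
  for (j in seq_along(model$trees)) {
    b <- model$coefficients[j]
    if (!is.na(b) && b != 0)
      eta <- eta + b * eval_tree_columns(model$trees[[j]], Xm)
  }
  stats::plogis(eta)
}

#' Binomial deviance of a logic model on data
#'
#' \eqn{-2 \sum [y \log \hat p + (1-y) \log(1-\hat p)]} at the model's
#' fitted probabilities.
#'
#' @param model a `logic_model`.
#' @param X 0/1 predictor matrix or `binary_design`.
#' @param y 0/1 outcome vector.
#' @param normalize if `TRUE`, per-observation mean deviance.
#' @return nonnegative deviance.
#' @export
score_model <- function(model, X, y, normalize = FALSE) {
  bernoulli_deviance(predict_prob(model, X), y, normalize = normalize)
}

#' @export
print.logic_model <- function(x, digits = 3, ...) {
  p <- length(x$trees)
  cat("Logic regression model: ", p, " tree(s), n = ", x$n,
      ", deviance = ", format(x$deviance, digits = 7), "\n", sep = "")
  cat("  intercept: ", format(x$intercept, digits = digits), "\n", sep = "")
  for (j in seq_len(p)) {
    b <- x$coefficients[j]
    cat(sprintf("  L%d (beta = %s): %s\n", j,
                format(b, digits = digits),
                render_tree(x$trees[[j]], x$predictor_names)))
  }
  if (x$separation) cat("  [flag] separation: coefficients capped\n")
  invisible(x)
}
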