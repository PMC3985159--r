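# Exhaustive single-tree search at small scale.  Enumerates every Boolean
# tree with up to `max_leaves` (<= 3) leaves over all predictors and their
# complements, fitting the one-covariate logistic model in closed form from
# the 2x2 (tree value x outcome) table.  Combinatorially infeasible beyond
# toy sizes, but on <= 8 predictors it delivers the certified global
# deviance minimum that the simulated-annealing search is validated
# against.

#' Exhaustively find the best single logic tree
#'
#' @param X n x k 0/1 predictor matrix (or `binary_design`), k small.
#' @param y 0/1 outcome vector.
#' @param max_leaves 1, 2, or 3.
#' @return list with `tree` (a `logic_tree` attaining the minimum),
#'   `deviance`, and `n_evaluated` (number of candidate trees scored).
#' @export
exhaustive_search <- function(X, y, max_leaves = 3L) {
  if (inherits(X, "binary_design") && is.null(y)) y <- X$y
  Xm <- design_matrix(X)
  k <- ncol(Xm)
  stopifnot(max_leaves >= 1L, max_leaves <= 3L)
  if (k > 12L) stop("exhaustive search is limited to 12 predictors")
  y <- as.integer(y != 0)
  n <- length(y)

  # leaf columns: predictor j plain (slot j) and complemented (slot k + j)
  L <- matrix(FALSE, n, 2L * k)
  for (j in seq_len(k)) {
    v <- Xm[, j] != 0
    L[, j] <- v
    L[, k + j] <- !v
  }
  leaf_of <- function(s) if (s <= k) logic_leaf(s) else logic_leaf(s - k, neg = TRUE)

  dev_of <- function(v) {
    a <- sum(y[v]); b <- sum(v) - a
    c_ <- sum(y) - a; d <- n - a - b - c_
    dev_cell <- function(s, f) {
      if (s + f == 0L) return(0)
      p <- s / (s + f)
      -2 * ((if (s > 0) s * log(p) else 0) + (if (f > 0) f * log(1 - p) else 0))
    }
    dev_cell(a, b) + dev_cell(c_, d)
  }

  best <- list(tree = NULL, deviance = Inf)
  n_eval <- 0L
  consider <- function(tree, v) {
    n_eval <<- n_eval + 1L
    d <- dev_of(v)
    if (d < best$deviance - 1e-12) best <<- list(tree = tree, deviance = d)
  }

  slots <- seq_len(2L * k)
  for (s1 in slots) consider(leaf_of(s1), L[, s1])
  if (max_leaves >= 2L) {
    for (s1 in slots) for (s2 in slots) {
      consider(logic_op("and", leaf_of(s1), leaf_of(s2)), L[, s1] & L[, s2])
      consider(logic_op("or", leaf_of(s1), leaf_of(s2)), L[, s1] | L[, s2])
    }
  }
  if (max_leaves >= 3L) {
    # by commutativity, shape leaf-op-(leaf op leaf) over ordered triples
    # covers every 3-leaf Boolean function
    for (s2 in slots) for (s3 in slots) {
      sub_and <- L[, s2] & L[, s3]
      sub_or <- L[, s2] | L[, s3]
      for (s1 in slots) {
        consider(logic_op("and", leaf_of(s1),
                          logic_op("and", leaf_of(s2), leaf_of(s3))),
                 L[, s1] & sub_and)
        consider(logic_op("and", leaf_of(s1),
                          logic_op("or", leaf_of(s2), leaf_of(s3))),
                 L[, s1] & sub_or)
        consider(logic_op("or", leaf_of(s1),
                          logic_op("and", leaf_of(s2), leaf_of(s3))),
                 L[, s1] | sub_and)
        consider(logic_op("or", leaf_of(s1),
                          logic_op("or", leaf_of(s2), leaf_of(s3))),
                 L[, s1] | sub_or)
      }
    }
  }
  list(tree = best$tree, deviance = best$deviance, n_evaluated = n_eval)
}
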