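#' Logic-tree constructors
#'
#' A logic tree is a full binary tree representing one Boolean expression:
#' leaves are (possibly complemented) binary predictors, internal nodes
#' ("knots") are AND/OR operators.  One tree corresponds to one Boolean
#' covariate \eqn{L_j} in the logistic model
#' \eqn{\mathrm{logit}\,P(Y=1) = \beta_0 + \beta_1 L_1 + \dots + \beta_p L_p}.
#'
#' Complement ("not") is carried on leaves only; any and/or/not formula can be
#' rewritten into this form via De Morgan's laws.
#'
#' @param index 1-based predictor (column) index into the bound design.
#' @param neg logical; if `TRUE` the leaf evaluates to NOT predictor.
#' @param op `"and"` or `"or"`.
#' @param left,right child nodes (leaves or operator nodes).
#' @return A `logic_tree` object (nested list).
#' @examples
#' # (X1 and (X2 or not X3))
#' tr <- logic_op("and", logic_leaf(1), logic_op("or", logic_leaf(2), logic_leaf(3, neg = TRUE)))
#' leaf_count(tr)
#' @export
logic_leaf <- function(index, neg = FALSE) {
  stopifnot(length(index) == 1L, is.finite(index), index >= 1)
  structure(list(leaf = as.integer(index), neg = isTRUE(neg)),
            class = "logic_tree")
}

#' @rdname logic_leaf
#' @export
logic_op <- function(op = c("and", "or"), left, right) {
  op <- match.arg(op)
  stopifnot(is_logic_node(left), is_logic_node(right))
  structure(list(op = op, left = left, right = right), class = "logic_tree")
}

is_logic_node <- function(x) {
  is.list(x) && (!is.null(x$leaf) || !is.null(x$op))
}

is_leaf <- function(node) !is.null(node$leaf)

#' Number of leaves in a logic tree
#' @param tree a `logic_tree`.
#' @return integer leaf count (>= 1).
#' @export
leaf_count <- function(tree) {
  if (is_leaf(tree)) return(1L)
  leaf_count(tree$left) + leaf_count(tree$right)
}

#' Predictor indices referenced by a tree
#' @param tree a `logic_tree`.
#' @return sorted unique integer vector of predictor indices.
#' @export
tree_predictors <- function(tree) {
  gather <- function(node) {
    if (is_leaf(node)) return(node$leaf)
    c(gather(node$left), gather(node$right))
  }
  sort(unique(gather(tree)))
}

#' Evaluate a logic tree on one row of binary predictors
#'
#' Recursive AND/OR of (possibly complemented) leaf values; `L = 1` is true
#' and `L = 0` is false.
#'
#' @param tree a `logic_tree`.
#' @param row numeric/logical 0/1 vector; positions are predictor indices.
#' @return 0 or 1.
#' @export
eval_tree <- function(tree, row) {
  idx <- tree_predictors(tree)
  if (length(row) < max(idx))
    stop("evaluation error: row has length ", length(row),
         " but tree references predictor ", max(idx))
  rec <- function(node) {
    if (is_leaf(node)) {
      v <- row[node$leaf] != 0
      return(if (node$neg) !v else v)
    }
    l <- rec(node$left); r <- rec(node$right)
    if (node$op == "and") l && r else l || r
  }
  as.integer(rec(tree))
}

#' Evaluate a logic tree down the columns of a design matrix
#'
#' Vectorised equivalent of [eval_tree()] applied to every row.
#'
#' @param tree a `logic_tree`.
#' @param X n x k 0/1 matrix (or a `binary_design`).
#' @return integer 0/1 vector of length n (length 0 for an empty design).
#' @export
eval_tree_columns <- function(tree, X) {
  X <- design_matrix(X)
  idx <- tree_predictors(tree)
  if (ncol(X) < max(idx))
    stop("evaluation error: design has ", ncol(X),
         " columns but tree references predictor ", max(idx))
  rec <- function(node) {
    if (is_leaf(node)) {
      v <- X[, node$leaf] != 0
      return(if (node$neg) !v else v)
    }
    if (node$op == "and") rec(node$left) & rec(node$right)
    else rec(node$left) | rec(node$right)
  }
  as.integer(rec(tree))
}

# Accept plain matrices or binary_design objects everywhere.
design_matrix <- function(X) {
  if (inherits(X, "binary_design")) X$X else as.matrix(X)
}

#' Truth table of a logic tree
#'
#' Brute-force enumeration of the tree's value over all 2^m assignments of
#' its m distinct predictors.  Used as the equivalence oracle.
#'
#' @param tree a `logic_tree`.
#' @param predictors optional integer vector of predictor indices to
#'   enumerate over (must cover the tree's own predictors); defaults to the
#'   tree's predictors.
#' @return list with `predictors`, `assignments` (2^m x m 0/1 matrix, one
#'   column per predictor in order), and `value` (0/1 vector of length 2^m).
#' @export
truth_table <- function(tree, predictors = NULL) {
  own <- tree_predictors(tree)
  preds <- if (is.null(predictors)) own else sort(unique(as.integer(predictors)))
  if (!all(own %in% preds))
    stop("predictors must cover all predictors referenced by the tree")
  m <- length(preds)
  if (m > 20L)
    stop("refusing truth table over ", m, " predictors (limit 20)")
  n <- 2L^m
  A <- matrix(0L, n, m)
  for (j in seq_len(m)) A[, j] <- rep(rep(0:1, each = 2L^(m - j)), length.out = n)
  # widen to a design the tree can index into directly
  X <- matrix(0L, n, max(preds))
  X[, preds] <- A
  list(predictors = preds, assignments = A, value = eval_tree_columns(tree, X))
}

#' Test Boolean equivalence of two logic trees
#'
#' Compares truth tables over the union of referenced predictors.
#'
#' @param t1,t2 `logic_tree` objects.
#' @return logical flag.
#' @export
trees_equivalent <- function(t1, t2) {
  preds <- sort(unique(c(tree_predictors(t1), tree_predictors(t2))))
  identical(truth_table(t1, preds)$value, truth_table(t2, preds)$value)
}

#' Draw a random logic tree
#'
#' Grows a tree to exactly `k_leaves` leaves by repeatedly splitting a random
#' leaf; predictors and complement flags drawn uniformly.  Uses the current
#' RNG state.
#'
#' @param k_leaves number of leaves (>= 1).
#' @param n_predictors number of predictors available.
#' @return a `logic_tree`.
#' @export
random_tree <- function(k_leaves, n_predictors) {
  stopifnot(k_leaves >= 1, n_predictors >= 1)
  rleaf <- function() logic_leaf(sample.int(n_predictors, 1L),
                                 neg = stats::runif(1) < 0.5)
  tree <- rleaf()
  while (leaf_count(tree) < k_leaves) {
    paths <- node_paths(tree, leaves_only = TRUE)
    p <- paths[[sample.int(length(paths), 1L)]]
    old <- get_node(tree, p)
    tree <- set_node(tree, p,
                     logic_op(if (stats::runif(1) < 0.5) "and" else "or",
                              old, rleaf()))
  }
  tree
}

#' Render a logic tree as a parseable and/or/not expression
#'
#' @param tree a `logic_tree`.
#' @param names optional character vector of predictor names; defaults to
#'   `X1`, `X2`, ...
#' @return a string such as `"(X1 and (X2 or not X3))"`, parseable back to an
#'   equivalent tree by [parse_tree()].
#' @export
render_tree <- function(tree, names = NULL) {
  nm <- function(i) {
    if (is.null(names)) paste0("X", i)
    else if (i <= length(names)) names[i]
    else stop("no name for predictor ", i)
  }
  rec <- function(node) {
    if (is_leaf(node)) {
      s <- nm(node$leaf)
      return(if (node$neg) paste("not", s) else s)
    }
    paste0("(", rec(node$left), " ", node$op, " ", rec(node$right), ")")
  }
  rec(tree)
}

#' Complement of a logic tree
#'
#' De Morgan rewrite of NOT(tree): operators flip between AND and OR and
#' every leaf's complement flag is toggled.  In a logistic model, a tree and
#' its complement describe the same fit with the coefficient's sign flipped
#' (and the intercept shifted), so planted rules are identified up to
#' complementation.
#'
#' @param tree a `logic_tree`.
#' @return the complemented `logic_tree`.
#' @export
complement_tree <- function(tree) {
  if (is_leaf(tree)) return(logic_leaf(tree$leaf, !tree$neg))
  logic_op(if (tree$op == "and") "or" else "and",
           complement_tree(tree$left), complement_tree(tree$right))
}

#' Parse an and/or/not expression into a logic tree
#'
#' Inverse of [render_tree()].  Grammar: a term is a (possibly
#' `not`-prefixed) predictor name or a parenthesised `(term op term)` with
#' `op` one of `and`, `or`.  `not` may also prefix a parenthesised group, in
#' which case De Morgan's laws push the complement down to the leaves.
#'
#' @param text expression string.
#' @param names character vector mapping predictor names to column indices;
#'   if `NULL`, names of the form `X<k>` map to index k.
#' @return a `logic_tree`.
#' @export
parse_tree <- function(text, names = NULL) {
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  resolve <- function(name) {
    if (!is.null(names)) {
      i <- match(name, names)
      if (is.na(i)) stop("unknown predictor name: ", name)
      return(i)
    }
    if (grepl("^X[0-9]+$", name)) return(as.integer(sub("^X", "", name)))
    stop("unknown predictor name: ", name)
  }
  term <- function() {
    t <- take()
    if (is.na(t)) stop("parse error: unexpected end of expression")
    if (t == "not") return(complement_tree(term()))
    if (t == "(") {
      l <- term()
      op <- take()
      if (!op %in% c("and", "or")) stop("parse error: expected and/or, got ", op)
      r <- term()
      if (!identical(take(), ")")) stop("parse error: expected ')'")
      return(logic_op(op, l, r))
    }
    logic_leaf(resolve(t))
  }
  out <- term()
  if (!is.na(peek())) stop("parse error: trailing input from '", peek(), "'")
  out
}

#' @export
print.logic_tree <- function(x, ...) {
  cat("<logic_tree> ", render_tree(x), "  [", leaf_count(x), " leaves]\n",
      sep = "")
  invisible(x)
}

# ---- node addressing (internal) --------------------------------------------
# A path is an integer vector of 1 (left) / 2 (right) steps from the root;
# integer(0) addresses the root itself.

node_paths <- function(tree, leaves_only = FALSE, internal_only = FALSE) {
  out <- list()
  rec <- function(node, path) {
    if (is_leaf(node)) {
      if (!internal_only) out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    if (!leaves_only) out[[length(out) + 1L]] <<- path
    rec(node$left, c(path, 1L))
    rec(node$right, c(path, 2L))
  }
  rec(tree, integer(0))
  out
}

get_node <- function(tree, path) {
  node <- tree
  for (s in path) node <- if (s == 1L) node$left else node$right
  node
}

set_node <- function(tree, path, value) {
  if (length(path) == 0L) {
    class(value) <- "logic_tree"
    return(value)
  }
  side <- if (path[1] == 1L) "left" else "right"
  tree[[side]] <- set_node(tree[[side]], path[-1], value)
  tree
}
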