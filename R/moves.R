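# Moves perturbing a logic tree.  The simulated-annealing chain proposes one
# of six kinds at random; each kind has an inverse kind so the chain can
# always return (alternate moves are self-inverse, grow <-> prune,
# split <-> delete).

MOVE_KINDS <- c("alternate-leaf", "alternate-operator",
                "grow-branch", "prune-branch",
                "split-leaf", "delete-leaf")

#' Construct a move on a logic tree
#'
#' @param kind one of `"alternate-leaf"`, `"alternate-operator"`,
#'   `"grow-branch"`, `"prune-branch"`, `"split-leaf"`, `"delete-leaf"`.
#' @param path integer vector addressing the target node from the root
#'   (1 = left, 2 = right; `integer(0)` is the root).
#' @param payload kind-specific replacement payload:
#'   `alternate-leaf` needs `list(index =, neg =)`;
#'   `grow-branch` / `split-leaf` need `list(op =, index =, neg =)`;
#'   the remaining kinds need none.
#' @return a `logic_move` object.
#' @export
logic_move <- function(kind, path = integer(0), payload = NULL) {
  kind <- match.arg(kind, MOVE_KINDS)
  structure(list(kind = kind, path = as.integer(path), payload = payload),
            class = "logic_move")
}

#' Apply a move to a logic tree
#'
#' Move semantics (leaf-count effect in brackets):
#' \describe{
#'   \item{alternate-leaf}{replace the target leaf's predictor/complement [0]}
#'   \item{alternate-operator}{flip the target knot between AND and OR [0]}
#'   \item{grow-branch}{wrap the target subtree in a new knot with a fresh
#'     leaf sibling: `T -> op(T, leaf)` [+1]}
#'   \item{prune-branch}{remove a knot whose target-addressed child is a
#'     leaf, promoting the sibling subtree [-1]}
#'   \item{split-leaf}{replace the target leaf by `op(leaf, new leaf)` [+1]}
#'   \item{delete-leaf}{remove the target leaf, promoting its sibling [-1]}
#' }
#' `prune-branch`/`delete-leaf` address the leaf being removed; both refuse
#' to empty the tree.
#'
#' @param tree a `logic_tree`.
#' @param move a `logic_move`.
#' @return the perturbed `logic_tree`.
#' @export
apply_move <- function(tree, move) {
  stopifnot(inherits(move, "logic_move"))
  node <- tryCatch(get_node(tree, move$path),
                   error = function(e) stop("move error: bad path"))
  pl <- move$payload
  switch(move$kind,
    "alternate-leaf" = {
      if (!is_leaf(node)) stop("move error: alternate-leaf needs a leaf target")
      set_node(tree, move$path, logic_leaf(pl$index, pl$neg))
    },
    "alternate-operator" = {
      if (is_leaf(node)) stop("move error: alternate-operator needs a knot target")
      node$op <- if (node$op == "and") "or" else "and"
      set_node(tree, move$path, node)
    },
    "grow-branch" = {
      set_node(tree, move$path,
               logic_op(pl$op, node, logic_leaf(pl$index, pl$neg)))
    },
    "prune-branch" = ,
    "delete-leaf" = {
      if (!is_leaf(node)) stop("move error: target must be the leaf to remove")
      if (length(move$path) == 0L)
        stop("move error: cannot empty a single-leaf tree")
      parent_path <- move$path[-length(move$path)]
      parent <- get_node(tree, parent_path)
      sibling <- if (move$path[length(move$path)] == 1L) parent$right else parent$left
      set_node(tree, parent_path, sibling)
    },
    "split-leaf" = {
      if (!is_leaf(node)) stop("move error: split-leaf needs a leaf target")
      set_node(tree, move$path,
               logic_op(pl$op, node, logic_leaf(pl$index, pl$neg)))
    })
}

# Kinds applicable to `tree` under a leaf budget (max leaves for this tree).
applicable_kinds <- function(tree, max_leaves) {
  k <- leaf_count(tree)
  kinds <- "alternate-leaf"
  if (k > 1L) kinds <- c(kinds, "alternate-operator", "prune-branch", "delete-leaf")
  if (k < max_leaves) kinds <- c(kinds, "grow-branch", "split-leaf")
  kinds
}

# Draw a random applicable move (uniform over applicable kinds, then uniform
# over eligible targets).  Uses the current RNG state.
propose_move <- function(tree, n_predictors, max_leaves,
                         kinds = applicable_kinds(tree, max_leaves)) {
  kind <- kinds[sample.int(length(kinds), 1L)]
  rand_leaf_payload <- function(op = FALSE) {
    pl <- list(index = sample.int(n_predictors, 1L),
               neg = stats::runif(1) < 0.5)
    if (op) pl$op <- if (stats::runif(1) < 0.5) "and" else "or"
    pl
  }
  pick <- function(paths) paths[[sample.int(length(paths), 1L)]]
  switch(kind,
    "alternate-leaf" = {
      p <- pick(node_paths(tree, leaves_only = TRUE))
      cur <- get_node(tree, p)
      repeat {
        pl <- rand_leaf_payload()
        if (pl$index != cur$leaf || pl$neg != cur$neg) break
      }
      logic_move(kind, p, pl)
    },
    "alternate-operator" = logic_move(kind, pick(node_paths(tree, internal_only = TRUE))),
    "grow-branch" = logic_move(kind, pick(node_paths(tree)), rand_leaf_payload(op = TRUE)),
    "split-leaf" = logic_move(kind, pick(node_paths(tree, leaves_only = TRUE)),
                              rand_leaf_payload(op = TRUE)),
    "prune-branch" = ,
    "delete-leaf" = logic_move(kind, pick(node_paths(tree, leaves_only = TRUE))))
}
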