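# Boolean tree semantics: evaluation, truth tables, equivalence, moves,
# rendering/parsing.

test_that("eval_tree implements and/or/not semantics on single rows", {
  conj <- parse_tree("(X1 and (X2 and (X3 and X4)))")
  expect_equal(eval_tree(conj, c(1, 1, 1, 1)), 1)
  expect_equal(eval_tree(conj, c(1, 1, 1, 0)), 0)

  # "X5 or X6 but not X7": true when all three are false (not X7 holds)
  disj <- parse_tree("(X5 or (X6 or not X7))")
  row <- numeric(7)
  expect_equal(eval_tree(disj, row), 1)
  row[7] <- 1
  expect_equal(eval_tree(disj, row), 0)

  expect_equal(eval_tree(logic_leaf(1, neg = TRUE), 1), 0)
  expect_equal(eval_tree(logic_leaf(1, neg = TRUE), 0), 1)
  expect_error(eval_tree(logic_leaf(3), c(1, 0)), "evaluation error")
})

test_that("eval_tree_columns agrees with per-row evaluation", {
  set.seed(11)
  for (i in 1:5) {
    tree <- random_tree(sample(1:5, 1), 6)
    X <- matrix(rbinom(100 * 6, 1, 0.5), 100, 6)
    col <- eval_tree_columns(tree, X)
    by_row <- vapply(seq_len(nrow(X)), function(r) eval_tree(tree, X[r, ]),
                     integer(1))
    expect_identical(col, by_row)
  }
  # tautology and empty design
  taut <- parse_tree("(X1 or not X1)")
  expect_identical(eval_tree_columns(taut, matrix(0:1, 2, 1)), c(1L, 1L))
  expect_identical(eval_tree_columns(logic_leaf(1),
                                     matrix(integer(0), 0, 2)), integer(0))
})

test_that("truth tables enumerate assignments and witness De Morgan", {
  tt <- truth_table(parse_tree("(X1 and X2)"))
  expect_equal(nrow(tt$assignments), 4)
  expect_identical(tt$value, c(0L, 0L, 0L, 1L))  # 00, 01, 10, 11

  leaf <- truth_table(logic_leaf(3))
  expect_identical(leaf$value, 0:1)

  set.seed(21)
  for (i in 1:10) {
    t1 <- random_tree(sample(1:6, 1), 8)
    expect_true(trees_equivalent(t1, complement_tree(complement_tree(t1))))
    expect_identical(truth_table(complement_tree(t1),
                                 tree_predictors(t1))$value,
                     1L - truth_table(t1)$value)
  }
  expect_true(trees_equivalent(parse_tree("not (X1 and X2)"),
                               parse_tree("(not X1 or not X2)")))
  expect_false(trees_equivalent(parse_tree("(X1 and X2)"),
                                parse_tree("(X1 or X2)")))
  big <- random_tree(2, 3)
  expect_error(truth_table(big, predictors = 1:25), "limit 20")
})

test_that("moves keep trees valid and account for leaves", {
  expect_equal(render_tree(apply_move(parse_tree("(X1 and X2)"),
                                      logic_move("alternate-operator"))),
               "(X1 or X2)")
  # split-leaf payload (or, X3): X1 -> (X1 or X3)
  split <- apply_move(logic_leaf(1),
                      logic_move("split-leaf", payload = list(op = "or",
                                                              index = 3,
                                                              neg = FALSE)))
  expect_equal(render_tree(split), "(X1 or X3)")
  expect_equal(leaf_count(split), 2)
  # delete-leaf on a two-leaf tree promotes the sibling to root
  expect_equal(render_tree(apply_move(parse_tree("(X1 and X2)"),
                                      logic_move("delete-leaf", path = 2L))),
               "X1")
  expect_error(apply_move(logic_leaf(1), logic_move("delete-leaf")),
               "move error")
  expect_error(apply_move(parse_tree("(X1 and X2)"),
                          logic_move("alternate-operator", path = 1L)),
               "move error")

  # leaf-count bookkeeping over many random proposals
  set.seed(31)
  tree <- random_tree(1, 5)
  for (i in 1:300) {
    mv <- boolereg:::propose_move(tree, 5, 6)
    new <- apply_move(tree, mv)
    diff <- leaf_count(new) - leaf_count(tree)
    expected <- switch(mv$kind,
                       "alternate-leaf" = 0L, "alternate-operator" = 0L,
                       "grow-branch" = 1L, "split-leaf" = 1L,
                       "prune-branch" = -1L, "delete-leaf" = -1L)
    expect_identical(diff, expected)
    expect_lte(leaf_count(new), 6)
    tree <- new
  }
})

test_that("every move has an inverse restoring the original tree", {
  set.seed(41)
  for (i in 1:50) {
    tree <- random_tree(sample(1:4, 1), 5)
    mv <- boolereg:::propose_move(tree, 5, 6)
    new <- apply_move(tree, mv)
    inverse <- switch(mv$kind,
      "alternate-operator" = logic_move("alternate-operator", mv$path),
      "alternate-leaf" = {
        old <- boolereg:::get_node(tree, mv$path)
        logic_move("alternate-leaf", mv$path,
                   list(index = old$leaf, neg = old$neg))
      },
      "grow-branch" = logic_move("delete-leaf", c(mv$path, 2L)),
      "split-leaf" = logic_move("delete-leaf", c(mv$path, 2L)),
      "delete-leaf" = ,
      "prune-branch" = {
        # regrow the removed leaf at the sibling position it vacated
        old <- boolereg:::get_node(tree, mv$path)
        parent <- boolereg:::get_node(tree, mv$path[-length(mv$path)])
        side <- mv$path[length(mv$path)]
        sib_path <- mv$path[-length(mv$path)]
        pl <- list(op = parent$op, index = old$leaf, neg = old$neg)
        logic_move("grow-branch", sib_path, pl)
      })
    restored <- apply_move(new, inverse)
    expect_true(trees_equivalent(tree, restored))
  }
})

test_that("render/parse round-trips preserve truth tables", {
  set.seed(51)
  for (i in 1:20) {
    tree <- random_tree(sample(1:6, 1), 9)
    expect_true(trees_equivalent(tree, parse_tree(render_tree(tree))))
  }
  nms <- c("tumor_le4", "grad_le1980", "major_affil")
  tree <- parse_tree("(tumor_le4 and not grad_le1980)", names = nms)
  expect_equal(render_tree(tree, nms), "(tumor_le4 and not grad_le1980)")
  expect_error(parse_tree("(bogus and X1)", names = nms), "unknown predictor")
})

test_that("random_tree honours the requested leaf count", {
  set.seed(61)
  for (k in c(1, 2, 5, 9)) {
    tree <- random_tree(k, 4)
    expect_equal(leaf_count(tree), k)
    expect_true(all(tree_predictors(tree) <= 4))
  }
})
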