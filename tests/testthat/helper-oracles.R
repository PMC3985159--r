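# Independent oracles used across the suite.  These deliberately avoid the
# package's fitting/evaluation code paths: deviances come from closed-form
# saturated 2x2 arithmetic, tree values from direct recursive evaluation on
# plain R structures, AUC from explicit all-pairs concordance counting.

# Saturated deviance of the single-split logistic model: fitted
# probabilities are the within-group outcome rates of the 2x2 table.
oracle_split_deviance <- function(v, y) {
  v <- as.integer(v != 0)
  y <- as.integer(y != 0)
  a <- sum(y[v == 1]); b <- sum(v == 1) - a
  cc <- sum(y[v == 0]); d <- sum(v == 0) - cc
  cell <- function(s, f) {
    if (s + f == 0) return(0)
    p <- s / (s + f)
    -2 * ((if (s > 0) s * log(p) else 0) + (if (f > 0) f * log(1 - p) else 0))
  }
  cell(a, b) + cell(cc, d)
}

# Log cross-product ratio of the 2x2 (exposure x outcome) table.
oracle_log_or <- function(v, y) {
  a <- sum(y == 1 & v == 1); b <- sum(y == 0 & v == 1)
  cc <- sum(y == 1 & v == 0); d <- sum(y == 0 & v == 0)
  log((a * d) / (b * cc))
}

# All-pairs concordance probability (ties count one half).
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Random 0/1 design with a planted Boolean rule outcome.
make_planted_data <- function(n, k, rule_expr, beta, intercept, seed) {
  set.seed(seed)
  X <- matrix(rbinom(n * k, 1, 0.5), n, k)
  rule <- parse_tree(rule_expr)
  y <- rbinom(n, 1, plogis(intercept + beta * eval_tree_columns(rule, X)))
  list(X = X, y = y, rule = rule)
}
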