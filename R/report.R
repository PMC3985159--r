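# Descriptive reporting: procedure cross-tabulations with chi-square
# screens, ROC/AUC evaluation of fitted models, and rendered model reports
# (trees as expressions with odds ratios and Wald intervals).

#' Cross-tabulate a cohort variable against a column variable
#'
#' Cell counts with row percentages to one decimal (percentage =
#' 100 * cell / row total).
#'
#' @param cohort data frame.
#' @param row_var name of the row variable.
#' @param col_var name of the column variable (e.g. `"procedure"`).
#' @param row_levels,col_levels optional explicit level orders.
#' @return a `crosstab`: list with `counts` (integer matrix), `pct`
#'   (row percentages, one decimal), `row_totals`, and the variable names.
#' @examples
#' df <- data.frame(a = c("x", "x", "y"), b = c("u", "v", "u"))
#' crosstab(df, "a", "b")
#' @export
crosstab <- function(cohort, row_var, col_var,
                     row_levels = NULL, col_levels = NULL) {
  r <- as.character(cohort[[row_var]])
  c_ <- as.character(cohort[[col_var]])
  if (is.null(row_levels)) row_levels <- unique(r)
  if (is.null(col_levels)) col_levels <- unique(c_)
  counts <- table(factor(r, levels = row_levels),
                  factor(c_, levels = col_levels))
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  row_totals <- rowSums(counts)
  pct <- round(100 * counts / ifelse(row_totals == 0, NA, row_totals), 1)
  structure(list(counts = counts, pct = pct, row_totals = row_totals,
                 row_var = row_var, col_var = col_var),
            class = "crosstab")
}

#' Build a crosstab directly from a count matrix
#'
#' @param counts integer matrix (levels x columns).
#' @return a `crosstab`.
#' @export
crosstab_from_counts <- function(counts) {
  row_totals <- rowSums(counts)
  pct <- round(100 * counts / ifelse(row_totals == 0, NA, row_totals), 1)
  structure(list(counts = counts, pct = pct, row_totals = row_totals,
                 row_var = NULL, col_var = NULL),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  m <- matrix(sprintf("%d (%.1f)", x$counts, x$pct),
              nrow(x$counts), dimnames = dimnames(x$counts))
  print(cbind(total = x$row_totals, as.data.frame(m)))
  invisible(x)
}

#' Pearson chi-square test of a crosstab
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1),
#' expected counts from the margins.  A `low_expected` flag (with a
#' warning) marks tables with any expected cell below 1.
#'
#' @param ct a `crosstab` or count matrix.
#' @return list with `statistic`, `df`, `p_value`, `expected`,
#'   `low_expected`.
#' @export
chisq_screen <- function(ct) {
  counts <- if (inherits(ct, "crosstab")) ct$counts else as.matrix(ct)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  low <- any(expected < 1)
  if (low) warning("chi-square screen: expected cell count below 1")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = expected,
       low_expected = low)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability via the rank
#' statistic — the probability that a randomly chosen event outscores a
#' randomly chosen non-event, ties counting one half.  Exact under tied
#' scores and invariant to strictly monotone score transforms.
#'
#' @param scores predicted scores/probabilities.
#' @param y 0/1 outcome labels.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, y) {
  y <- as.integer(y != 0)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("auc needs both outcome classes")
  r <- rank(scores)  # midranks handle ties as 0.5
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Render a fitted logic model as a structured report
#'
#' Per tree: the and/or/not expression, odds ratio and Wald 95% interval;
#' plus the model deviance and ROC AUC on the supplied data.
#'
#' @param model a `logic_model`.
#' @param X 0/1 predictor matrix or `binary_design`.
#' @param y 0/1 outcome vector.
#' @param level confidence level for the intervals.
#' @return a `logic_report`: list with `trees` (data frame expression /
#'   coefficient / se / or / lower / upper), `intercept`, `deviance`,
#'   `auc`, `n`.
#' @export
render_model_report <- function(model, X, y = NULL, level = 0.95) {
  if (inherits(X, "binary_design") && is.null(y)) y <- X$y
  Xm <- design_matrix(X)
  p <- length(model$trees)
  rows <- lapply(seq_len(p), function(j) {
    b <- model$coefficients[j]
    se <- model$se[j + 1L]
    ci <- if (!is.na(b) && !is.na(se)) odds_ratio_ci(b, se, level)
          else c(or = NA_real_, lower = NA_real_, upper = NA_real_)
    data.frame(tree = j,
               expression = render_tree(model$trees[[j]],
                                        model$predictor_names),
               coefficient = b, se = se,
               or = unname(ci["or"]), lower = unname(ci["lower"]),
               upper = unname(ci["upper"]))
  })
  structure(list(trees = do.call(rbind, rows),
                 intercept = model$intercept,
                 deviance = score_model(model, Xm, y),
                 auc = auc(predict_prob(model, Xm), y),
                 n = nrow(Xm)),
            class = "logic_report")
}

#' @export
print.logic_report <- function(x, ...) {
  cat("Logic regression report (n = ", x$n, ")\n", sep = "")
  cat("  deviance: ", format(x$deviance, digits = 7),
      "   AUC: ", format(x$auc, digits = 3), "\n", sep = "")
  for (i in seq_len(nrow(x$trees))) {
    r <- x$trees[i, ]
    cat(sprintf("  L%d: %s\n      OR %.2f (95%% CI %.2f-%.2f)\n",
                r$tree, r$expression, r$or, r$lower, r$upper))
  }
  invisible(x)
}

#' Write a model report as JSON-ready list / CSV
#'
#' @param report a `logic_report`.
#' @param path CSV path for the per-tree table.
#' @export
write_model_report <- function(report, path) {
  utils::write.csv(report$trees, path, row.names = FALSE)
  invisible(path)
}
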