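# Maximum-likelihood logistic regression with 0/1 covariate columns, scored
# by binomial deviance.  Because every covariate is binary, the Bernoulli
# likelihood depends on the data only through the 2^p cell counts of the
# covariate pattern x outcome cross-classification, so the IRLS runs on the
# collapsed table (<= 2^p rows) rather than the n raw rows.  This is exact
# and is what keeps a full refit per annealing proposal affordable.

#' Fit logistic-regression coefficients for 0/1 covariate columns
#'
#' Iteratively reweighted least squares on the collapsed covariate-pattern
#' table; convergence declared when the deviance changes by less than `tol`
#' (default 1e-8), at most `max_iter` iterations.  Complete separation is
#' detected and handled by capping each fitted log-odds at +/- `beta_cap`
#' (a slope may reach twice the cap when the two groups separate in opposite
#' directions) with a `separation` flag (a warning if `warn = TRUE`) rather
#' than failing, so a
#' search chain proposing rare Boolean combinations stays alive.  Columns
#' that are constant, or duplicates of an earlier column, are dropped from
#' the fit (coefficient reported as `NA`) and flagged.
#'
#' @param columns list of 0/1 vectors (or an n x p 0/1 matrix); may be empty
#'   for an intercept-only fit.
#' @param y 0/1 outcome vector of the same length.
#' @param tol convergence tolerance on the deviance change.
#' @param max_iter maximum IRLS iterations.
#' @param beta_cap absolute cap applied to coefficients under separation.
#' @param warn warn on separation / dropped columns.
#' @return list with `coefficients` (intercept first, `NA` for dropped
#'   columns), `se` (standard errors, same layout), `deviance`
#'   (\eqn{-2 \times} log-likelihood at the optimum), `converged`, `dropped`
#'   (indices of dropped covariate columns), and `separation`.
#' @examples
#' set.seed(1)
#' x <- rbinom(500, 1, 0.4)
#' y <- rbinom(500, 1, plogis(-1 + 1.2 * x))
#' fit_coefficients(list(x), y)$coefficients
#' @export
fit_coefficients <- function(columns, y, tol = 1e-8, max_iter = 100L,
                             beta_cap = 15, warn = TRUE) {
  if (is.matrix(columns)) {
    M <- columns
  } else if (length(columns) == 0L) {
    M <- matrix(0L, length(y), 0L)
  } else {
    M <- do.call(cbind, columns)
  }
  n <- length(y)
  stopifnot(n >= 1L, nrow(M) == n)
  y <- as.integer(y != 0)
  p <- ncol(M)

  # drop constant and duplicate columns
  keep <- logical(p)
  seen <- list()
  for (j in seq_len(p)) {
    v <- M[, j]
    if (all(v == v[1])) next
    dup <- FALSE
    for (s in seen) if (identical(M[, s], v)) { dup <- TRUE; break }
    if (dup) next
    keep[j] <- TRUE
    seen[[length(seen) + 1L]] <- j
  }
  dropped <- which(!keep)
  if (warn && length(dropped))
    warning("dropping ", length(dropped),
            " constant/duplicate covariate column(s) from the fit")

  fit <- if (sum(keep) == 1L)
    fit_2x2(M[, which(keep)], y, beta_cap)
  else
    irls_collapsed(M[, keep, drop = FALSE], y, tol, max_iter, beta_cap)
  if (warn && fit$separation)
    warning("separation detected; fitted log-odds capped at |", beta_cap, "|")

  coefs <- se <- rep(NA_real_, p + 1L)
  coefs[c(1L, which(keep) + 1L)] <- fit$beta
  se[c(1L, which(keep) + 1L)] <- fit$se
  list(coefficients = coefs, se = se, deviance = fit$deviance,
       converged = fit$converged, dropped = dropped,
       separation = fit$separation)
}

# Exact closed-form MLE for one binary covariate: the fitted probabilities
# are the within-group outcome rates, so the coefficient is the log
# cross-product ratio of the 2x2 (covariate x outcome) table.  Zero cells
# (separation) are handled by the coefficient cap.
fit_2x2 <- function(v, y, beta_cap = 15) {
  v <- v != 0L
  a <- sum(y[v]); b <- sum(v) - a          # v = 1: events, non-events
  cc <- sum(y) - a; d <- length(y) - a - b - cc
  clamp <- function(x) pmin(pmax(x, -beta_cap), beta_cap)
  l1 <- if (a == 0L) -Inf else if (b == 0L) Inf else log(a / b)
  l0 <- if (cc == 0L) -Inf else if (d == 0L) Inf else log(cc / d)
  separation <- is.infinite(l0) || is.infinite(l1)
  # the cap applies to each group's fitted log-odds, so under two-sided
  # separation the slope may reach 2 * beta_cap while both fitted
  # probabilities stay strictly inside (0, 1)
  b0 <- clamp(l0)
  b1 <- clamp(l1) - b0
  p1 <- stats::plogis(b0 + b1); p0 <- stats::plogis(b0)
  dev <- binom_dev(c(a, cc), c(b, d), c(p1, p0))
  se <- c(sqrt(1 / cc + 1 / d), sqrt(1 / a + 1 / b + 1 / cc + 1 / d))
  list(beta = c(b0, b1), se = se, deviance = dev, converged = TRUE,
       separation = separation)
}

# IRLS on the collapsed pattern table.  M: n x q 0/1 matrix with no
# constant/duplicate columns; y: 0/1.  Returns beta (length q+1), se,
# deviance, converged, separation.
irls_collapsed <- function(M, y, tol = 1e-8, max_iter = 100L, beta_cap = 15,
                           start = NULL) {
  q <- ncol(M)
  n <- length(y)
  if (q == 0L) {
    s <- sum(y)
    ph <- s / n
    beta <- if (ph <= 0) -beta_cap else if (ph >= 1) beta_cap else log(ph / (1 - ph))
    dev <- binom_dev(s, n - s, stats::plogis(beta))
    se <- if (ph > 0 && ph < 1) sqrt(1 / (n * ph * (1 - ph))) else NA_real_
    return(list(beta = beta, se = se, deviance = dev, converged = TRUE,
                separation = (ph <= 0 || ph >= 1)))
  }
  # pattern id and collapsed counts
  id <- as.integer(M %*% 2^(seq_len(q) - 1L))
  tab1 <- tabulate(id[y == 1L] + 1L, nbins = 2L^q)
  tab0 <- tabulate(id[y == 0L] + 1L, nbins = 2L^q)
  tot <- tab0 + tab1
  use <- tot > 0L
  ids <- which(use) - 1L
  Xc <- cbind(1, vapply(seq_len(q), function(j) as.numeric(bitwAnd(ids, 2L^(j - 1L)) > 0),
                        numeric(length(ids))))
  s1 <- tab1[use]; nt <- tot[use]

  beta <- if (is.null(start)) numeric(q + 1L) else start
  dev <- collapsed_dev(Xc, beta, s1, nt)
  converged <- FALSE
  separation <- FALSE
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(Xc %*% beta)
    mu <- stats::plogis(eta)
    w <- nt * mu * (1 - mu)
    if (any(w < 1e-10)) w <- pmax(w, 1e-10)
    z <- eta + (s1 - nt * mu) / w
    XtWX <- crossprod(Xc, Xc * w)
    beta_new <- tryCatch(drop(solve(XtWX, crossprod(Xc, w * z))),
                         error = function(e) beta)
    if (max(abs(beta_new)) > beta_cap) {
      beta <- pmin(pmax(beta_new, -beta_cap), beta_cap)
      separation <- TRUE
      dev <- collapsed_dev(Xc, beta, s1, nt)
      break
    }
    dev_new <- collapsed_dev(Xc, beta_new, s1, nt)
    beta <- beta_new
    if (abs(dev - dev_new) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  # observed-information SEs at the final coefficients
  eta <- drop(Xc %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(nt * mu * (1 - mu), 1e-10)
  XtWX <- crossprod(Xc, Xc * w)
  se <- tryCatch(sqrt(diag(solve(XtWX))), error = function(e) rep(NA_real_, q + 1L))
  list(beta = beta, se = se, deviance = dev, converged = converged || separation,
       separation = separation)
}

collapsed_dev <- function(Xc, beta, s1, nt) {
  mu <- stats::plogis(drop(Xc %*% beta))
  binom_dev(s1, nt - s1, mu)
}

# -2 log-likelihood from per-cell success/failure counts and probabilities;
# 0 * log(0) treated as 0.
binom_dev <- function(s, f, mu) {
  t1 <- ifelse(s > 0, s * log(mu), 0)
  t0 <- ifelse(f > 0, f * log1p(-mu), 0)
  -2 * sum(t1 + t0)
}

#' Bernoulli deviance of a probability vector against 0/1 outcomes
#'
#' \eqn{-2 \sum [y \log \hat p + (1-y)\log(1-\hat p)]}.
#'
#' @param prob per-row probability vector in (0,1).
#' @param y 0/1 outcome vector.
#' @param normalize if `TRUE`, return the per-observation mean deviance.
#' @return nonnegative deviance.
#' @export
bernoulli_deviance <- function(prob, y, normalize = FALSE) {
  y <- as.integer(y != 0)
  d <- -2 * sum(ifelse(y == 1L, log(prob), log1p(-prob)))
  if (normalize) d / length(y) else d
}

#' Odds ratio with Wald confidence interval
#'
#' `OR = exp(beta)` with bounds `exp(beta +/- z * se)`, `z` the standard
#' normal quantile for the requested level — symmetric on the log-odds scale.
#'
#' @param coefficient log-odds coefficient.
#' @param se nonnegative standard error.
#' @param level confidence level (default 0.95).
#' @return named numeric vector `(or, lower, upper)`.
#' @export
odds_ratio_ci <- function(coefficient, se, level = 0.95) {
  stopifnot(se >= 0, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(coefficient),
    lower = exp(coefficient - z * se),
    upper = exp(coefficient + z * se))
}
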