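# Binary recoding of mixed-type cohort covariates.  Logic regression needs
# 0/1 predictors, so categorical covariates become sets of indicator columns
# and continuous/ordinal covariates become series of threshold-band
# indicators at clinically chosen cutpoints.  Bands are emitted as mutually
# exclusive one-hot indicators (the Boolean search can synthesise cumulative
# thresholds via OR).

#' Build a coding schema
#'
#' A coding schema maps each raw cohort variable to binary predictors.
#' Three kinds are supported:
#' \describe{
#'   \item{indicator-set}{one 0/1 column per listed level; values outside
#'     the listed levels go to the last level when `other = TRUE`, otherwise
#'     encoding fails.}
#'   \item{threshold-series}{ordered numeric cutpoints partition the raw
#'     value into bands (right-closed: value <= first cutpoint is band 1);
#'     one 0/1 column per band.  Raw values may also already be band
#'     labels.}
#'   \item{indicator}{a single 0/1 column for one level versus all others.}
#' }
#'
#' @param ... `schema_variable()` entries.
#' @return a `coding_schema` object (list of entries).
#' @seealso [build_default_schema()], [encode()]
#' @export
coding_schema <- function(...) {
  entries <- list(...)
  for (e in entries) stopifnot(inherits(e, "schema_variable"))
  nm <- vapply(entries, function(e) e$variable, character(1))
  if (anyDuplicated(nm)) stop("schema error: duplicate variable in schema")
  structure(stats::setNames(entries, nm), class = "coding_schema")
}

#' @rdname coding_schema
#' @param variable raw cohort column name.
#' @param kind `"indicator-set"`, `"threshold-series"`, or `"indicator"`.
#' @param levels level labels (indicator-set: all levels; threshold-series:
#'   band labels, one more than cutpoints; indicator: the single level).
#' @param cutpoints strictly increasing numeric cutpoints
#'   (threshold-series only).
#' @param other indicator-set only: route unseen levels to the last level.
#' @export
schema_variable <- function(variable,
                            kind = c("indicator-set", "threshold-series",
                                     "indicator"),
                            levels, cutpoints = NULL, other = FALSE) {
  kind <- match.arg(kind)
  if (kind == "threshold-series") {
    if (is.null(cutpoints) || is.unsorted(cutpoints, strictly = TRUE))
      stop("schema error: cutpoints must be strictly increasing")
    if (length(levels) != length(cutpoints) + 1L)
      stop("schema error: need one band label per interval")
  }
  if (kind == "indicator" && length(levels) != 1L)
    stop("schema error: indicator takes exactly one level")
  structure(list(variable = variable, kind = kind, levels = as.character(levels),
                 cutpoints = cutpoints, other = isTRUE(other)),
            class = "schema_variable")
}

#' Default coding schema for the kidney-cancer cohort
#'
#' Encodes the cohort covariates at the standard clinical cutpoints: tumor
#' size at the 4 cm threshold; patient age in five-year bands 65-69, 70-74,
#' 75-79, 80-84, >=85; Charlson comorbidity 0 / 1 / >=2; surgeon graduation
#' year <1960, 1961-1970, 1971-1980, 1981-1990, >=1991; surgeon age <40,
#' 40-49, 50-59, >=60; practice structure (solo or two-person, group, HMO or
#' hospital-based, medical school, other); academic affiliation none / minor
#' / major; plus married-vs-others, race/ethnicity indicators, rural vs
#' urban, NCI cancer-center affiliation, and the high-volume surgeon
#' indicator (>= 3 annual cancer-related nephrectomies, the caseload 83rd
#' percentile; computed by the cohort generator).
#'
#' @return a `coding_schema`.
#' @export
build_default_schema <- function() {
  coding_schema(
    schema_variable("tumor_size_cm", "threshold-series",
                    levels = c("<=4", ">4"), cutpoints = 4),
    schema_variable("age_at_surgery", "threshold-series",
                    levels = c("65-69", "70-74", "75-79", "80-84", ">=85"),
                    cutpoints = c(69, 74, 79, 84)),
    schema_variable("charlson_score", "threshold-series",
                    levels = c("0", "1", ">=2"), cutpoints = c(0, 1)),
    schema_variable("graduation_year", "threshold-series",
                    levels = c("<1960", "1961-1970", "1971-1980",
                               "1981-1990", ">=1991"),
                    cutpoints = c(1959, 1970, 1980, 1990)),
    schema_variable("surgeon_age", "threshold-series",
                    levels = c("<40", "40-49", "50-59", ">=60"),
                    cutpoints = c(39, 49, 59)),
    schema_variable("practice_size", "indicator-set",
                    levels = c("Solo or two-person", "Group practice",
                               "HMO or hospital-based", "Medical school",
                               "Other/unclassified"),
                    other = TRUE),
    schema_variable("academic_affiliation", "indicator-set",
                    levels = c("None", "Minor", "Major")),
    schema_variable("married", "indicator", levels = "Yes"),
    schema_variable("race_ethnicity", "indicator-set",
                    levels = c("Caucasian", "African-American", "Hispanic",
                               "Other or Unknown"),
                    other = TRUE),
    schema_variable("rural_urban", "indicator", levels = "Rural"),
    schema_variable("nci_center", "indicator", levels = "Yes"),
    schema_variable("high_volume", "indicator", levels = "Yes"))
}

# Band label for raw values under a threshold-series entry.  Numeric input
# is cut at the cutpoints (right-closed); character/factor input must
# already be band labels.
band_of <- function(x, entry) {
  if (is.numeric(x)) {
    as.character(cut(x, breaks = c(-Inf, entry$cutpoints, Inf),
                     labels = entry$levels, right = TRUE))
  } else {
    x <- as.character(x)
    bad <- !is.na(x) & !(x %in% entry$levels)
    if (any(bad))
      stop("encoding error: value '", x[which(bad)[1]],
           "' is not a band of '", entry$variable, "'")
    x
  }
}

sanitize_level <- function(x) {
  x <- gsub("<=", "le", x, fixed = TRUE)
  x <- gsub(">=", "ge", x, fixed = TRUE)
  x <- gsub("<", "lt", x, fixed = TRUE)
  x <- gsub(">", "gt", x, fixed = TRUE)
  gsub("_+$|^_+", "", gsub("[^A-Za-z0-9]+", "_", x))
}

#' Encode a cohort into a binary design
#'
#' Applies a [coding_schema()] to a cohort data frame, producing the n x k
#' 0/1 predictor matrix logic regression operates on, together with a
#' provenance map from each encoded column back to its raw variable and
#' level.  Rows with missing values in any schema variable are excluded
#' (complete-case) with a message; columns that come out constant are
#' dropped with a warning.
#'
#' @param cohort data frame with one row per patient.
#' @param schema a `coding_schema`.
#' @param outcome optional name of a 0/1 outcome column to carry along.
#' @return a `binary_design`: list with `X` (0/1 integer matrix, named
#'   columns), `y` (0/1 outcome or `NULL`), `provenance` (data frame
#'   column/variable/level/kind), `dropped_columns`, `n_dropped_rows`, and
#'   `row_index` (rows of `cohort` retained).
#' @examples
#' cohort <- data.frame(tumor_size_cm = c(3.2, 5.1, 4.0),
#'                      academic_affiliation = c("None", "Major", "Minor"))
#' sch <- coding_schema(
#'   schema_variable("tumor_size_cm", "threshold-series",
#'                   levels = c("<=4", ">4"), cutpoints = 4),
#'   schema_variable("academic_affiliation", "indicator-set",
#'                   levels = c("None", "Minor", "Major")))
#' encode(cohort, sch)$X
#' @export
encode <- function(cohort, schema, outcome = NULL) {
  stopifnot(inherits(schema, "coding_schema"))
  missing_vars <- setdiff(vapply(schema, `[[`, character(1), "variable"),
                          names(cohort))
  if (length(missing_vars))
    stop("encoding error: cohort lacks variable(s): ",
         paste(missing_vars, collapse = ", "))

  # complete-case restriction over modeled variables (and outcome)
  check <- c(vapply(schema, `[[`, character(1), "variable"), outcome)
  complete <- stats::complete.cases(cohort[, check, drop = FALSE])
  n_dropped_rows <- sum(!complete)
  if (n_dropped_rows > 0)
    message("encode: excluding ", n_dropped_rows,
            " row(s) with missing values in modeled variables")
  cohort <- cohort[complete, , drop = FALSE]

  cols <- list()
  prov <- list()
  for (entry in schema) {
    raw <- cohort[[entry$variable]]
    if (entry$kind == "threshold-series") {
      lab <- band_of(raw, entry)
      levels <- entry$levels
    } else {
      lab <- as.character(raw)
      levels <- entry$levels
      unseen <- !(lab %in% levels)
      if (any(unseen)) {
        if (entry$kind == "indicator-set" && entry$other) {
          lab[unseen] <- levels[length(levels)]
        } else if (entry$kind == "indicator") {
          # anything not the named level is simply 0
        } else {
          stop("encoding error: unseen level '", lab[which(unseen)[1]],
               "' for '", entry$variable, "' and no 'other' bucket")
        }
      }
      if (entry$kind == "indicator") levels <- entry$levels
    }
    for (lv in levels) {
      cname <- paste0(entry$variable, "_", sanitize_level(lv))
      cols[[cname]] <- as.integer(lab == lv)
      prov[[cname]] <- data.frame(column = cname, variable = entry$variable,
                                  level = lv, kind = entry$kind,
                                  stringsAsFactors = FALSE)
    }
  }
  X <- do.call(cbind, cols)
  provenance <- do.call(rbind, c(prov, list(make.row.names = FALSE)))

  const <- which(apply(X, 2, function(v) all(v == v[1])))
  dropped_columns <- colnames(X)[const]
  if (length(const)) {
    warning("encode: dropping constant column(s): ",
            paste(dropped_columns, collapse = ", "))
    X <- X[, -const, drop = FALSE]
    provenance <- provenance[!(provenance$column %in% dropped_columns), ,
                             drop = FALSE]
  }

  y <- if (!is.null(outcome)) as.integer(cohort[[outcome]] != 0) else NULL
  structure(list(X = X, y = y, provenance = provenance,
                 dropped_columns = dropped_columns,
                 n_dropped_rows = n_dropped_rows,
                 row_index = which(complete)),
            class = "binary_design")
}

#' Reconstruct raw categories from an encoded design
#'
#' Inverts the encoding via the provenance map: for indicator-set and
#' threshold-series variables the active indicator gives the raw
#' category/band; for single-indicator variables rows without the level are
#' reported as `"not <level>"`.  Categories encoded by a column that was
#' dropped as constant are recovered as the (single) level no retained
#' column claims.
#'
#' @param design a `binary_design`.
#' @param variable raw variable name.
#' @return character vector of length n.
#' @export
decode_design <- function(design, variable) {
  prov <- design$provenance[design$provenance$variable == variable, ,
                            drop = FALSE]
  if (!nrow(prov)) stop("no encoded columns for variable '", variable, "'")
  n <- nrow(design$X)
  out <- rep(NA_character_, n)
  active <- matrix(0L, n, nrow(prov))
  for (i in seq_len(nrow(prov))) active[, i] <- design$X[, prov$column[i]]
  hit <- active %*% seq_len(nrow(prov))
  multi <- rowSums(active) > 1L
  if (any(multi)) stop("provenance violated: multiple active indicators")
  out[hit > 0] <- prov$level[hit[hit > 0]]
  if (any(hit == 0)) {
    if (prov$kind[1] == "indicator") {
      out[hit == 0] <- paste("not", prov$level[1])
    } else {
      # the level whose column was dropped as constant (if exactly one)
      dropped <- setdiff(
        paste0(variable, "_", sanitize_level(all_schema_levels(design, variable))),
        prov$column)
      out[hit == 0] <- if (length(dropped) == 1L)
        all_schema_levels(design, variable)[
          paste0(variable, "_",
                 sanitize_level(all_schema_levels(design, variable))) == dropped]
      else NA_character_
    }
  }
  out
}

# Levels (retained + dropped) known for a variable, from provenance and the
# dropped-column names.
all_schema_levels <- function(design, variable) {
  prov <- design$provenance[design$provenance$variable == variable, ,
                            drop = FALSE]
  lv <- prov$level
  pre <- paste0(variable, "_")
  extra <- design$dropped_columns[startsWith(design$dropped_columns, pre)]
  c(lv, sub(pre, "", extra, fixed = TRUE))
}

#' @export
print.binary_design <- function(x, ...) {
  cat("<binary_design> ", nrow(x$X), " rows x ", ncol(x$X), " binary predictors",
      if (!is.null(x$y)) paste0("; outcome rate ",
                                format(mean(x$y), digits = 3)), "\n", sep = "")
  invisible(x)
}

#' Read/write a coding schema as YAML
#'
#' @param schema a `coding_schema`.
#' @param path file path.
#' @return `read_schema()` returns a `coding_schema`; `write_schema()` the
#'   path, invisibly.
#' @export
write_schema <- function(schema, path) {
  yaml::write_yaml(lapply(unname(schema), function(e)
    list(variable = e$variable, kind = e$kind, levels = as.list(e$levels),
         cutpoints = if (is.null(e$cutpoints)) NULL else as.list(e$cutpoints),
         other = e$other)), path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(coding_schema, lapply(raw, function(e)
    schema_variable(e$variable, e$kind, levels = unlist(e$levels),
                    cutpoints = if (length(e$cutpoints)) unlist(e$cutpoints),
                    other = isTRUE(e$other))))
}

#' Write an encoded design as CSV with a provenance sidecar
#'
#' @param design a `binary_design`.
#' @param path CSV path for the 0/1 matrix (outcome appended as `y` when
#'   present); provenance written next to it as `<path>.provenance.csv`.
#' @return invisibly, the main path.
#' @export
write_design <- function(design, path) {
  df <- as.data.frame(design$X)
  if (!is.null(design$y)) df$y <- design$y
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(design$provenance,
                   paste0(sub("\\.csv$", "", path), ".provenance.csv"),
                   row.names = FALSE)
  invisible(path)
}
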