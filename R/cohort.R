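# Synthetic claims-registry cohort generator.  Emulates the structure of a
# linked registry-claims kidney-cancer cohort — ~12,000 patients nested in
# ~2,000 surgeons, mixed patient/surgeon/practice covariates, binary
# treatment endpoints — with outcome probabilities driven by planted Boolean
# rules through the logistic link, so that every downstream stage (recoding,
# tree search, cross-validation, reporting) is testable without restricted
# data.  Covariates are drawn independently at their marginal frequencies;
# continuous variables are drawn directly as category bands at the clinical
# cutpoints, since only the binarised versions enter the model.

#' Specify a synthetic cohort
#'
#' @param n_patients number of patients.
#' @param n_surgeons number of surgeons (<= `n_patients`).
#' @param variable_specs list of [cohort_variable()] entries.
#' @param seed integer master seed.  Each variable draws from its own
#'   RNG stream derived from (seed, variable name), so adding a variable
#'   does not perturb earlier columns.
#' @param caseload_shape geometric shape of the surgeon caseload
#'   distribution: expected caseload of a surgeon, before patient
#'   assignment.  Defaults to `n_patients / n_surgeons`, which at the
#'   default cohort scale gives the skewed many-low-volume-provider pattern
#'   (median caseload near 4).
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, n_surgeons, variable_specs, seed,
                        caseload_shape = n_patients / n_surgeons) {
  stopifnot(n_patients >= 1, n_surgeons >= 1, n_surgeons <= n_patients,
            caseload_shape >= 1)
  for (v in variable_specs) {
    stopifnot(inherits(v, "cohort_variable"))
    if (any(v$probs < 0) || abs(sum(v$probs) - 1) > 1e-9)
      stop("schema error: marginal probabilities of '", v$name,
           "' must be nonnegative and sum to 1")
  }
  nm <- vapply(variable_specs, function(v) v$name, character(1))
  structure(list(n_patients = as.integer(n_patients),
                 n_surgeons = as.integer(n_surgeons),
                 variable_specs = stats::setNames(variable_specs, nm),
                 seed = as.integer(seed),
                 caseload_shape = caseload_shape),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param name variable name.
#' @param kind `"categorical"`, `"ordinal"`, or `"continuous"` (metadata;
#'   continuous variables are generated as bands at their cutpoints).
#' @param levels category/band labels.
#' @param probs marginal probabilities (same length as `levels`, sum 1).
#' @param unit `"patient"` (drawn per patient) or `"surgeon"` (drawn once
#'   per surgeon and constant within surgeon).
#' @export
cohort_variable <- function(name, kind = c("categorical", "ordinal", "continuous"),
                            levels, probs, unit = c("patient", "surgeon")) {
  kind <- match.arg(kind)
  unit <- match.arg(unit)
  stopifnot(length(levels) == length(probs))
  structure(list(name = name, kind = kind, levels = as.character(levels),
                 probs = as.numeric(probs), unit = unit),
            class = "cohort_variable")
}

# Deterministic per-variable substream seed: polynomial string hash folded
# with the master seed, kept inside 32-bit integer range.
stream_seed <- function(seed, name) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483629
  as.integer((h + as.double(seed)) %% 2147483629)
}

#' Default synthetic cohort specification
#'
#' Marginal frequencies are taken from the embedded cross-tabulation
#' fixtures ([fixtures()]): patient variables from the patient/tumor table,
#' surgeon variables from the surgeon/practice table (patient-weighted
#' margins, applied per surgeon).  Defaults are the study-scale conditions:
#' 11,918 patients and 2,088 surgeons.
#'
#' @param n_patients,n_surgeons cohort scale.
#' @param seed master seed.
#' @return a `cohort_spec`.
#' @export
default_cohort_spec <- function(n_patients = 11918, n_surgeons = 2088,
                                seed = 20140327) {
  fx <- fixtures()
  marg <- function(table, variable, unit, kind = "categorical") {
    rows <- table[table$variable == variable, ]
    cohort_variable(variable, kind, rows$level, rows$total / sum(rows$total),
                    unit = unit)
  }
  cohort_spec(n_patients, n_surgeons, list(
    marg(fx$table1, "age_at_surgery", "patient", "continuous"),
    marg(fx$table1, "race_ethnicity", "patient"),
    marg(fx$table1, "gender", "patient"),
    marg(fx$table1, "married", "patient"),
    marg(fx$table1, "socioeconomic_status", "patient", "ordinal"),
    marg(fx$table1, "charlson_score", "patient", "ordinal"),
    marg(fx$table1, "tumor_size_cm", "patient", "continuous"),
    marg(fx$table1, "tumor_histology", "patient"),
    marg(fx$table2, "surgeon_age", "surgeon", "continuous"),
    marg(fx$table2, "surgeon_gender", "surgeon"),
    marg(fx$table2, "graduation_year", "surgeon", "continuous"),
    marg(fx$table2, "practice_size", "surgeon"),
    marg(fx$table2, "academic_affiliation", "surgeon", "ordinal"),
    marg(fx$table2, "rural_urban", "surgeon"),
    marg(fx$table2, "nci_center", "surgeon")),
    seed = seed)
}

#' Generate the covariate table of a synthetic cohort
#'
#' Patients are assigned to surgeons with probability proportional to
#' geometric-like surgeon weights, reproducing the skewed caseload
#' distribution of real provider data (many low-volume providers).
#' Patient-unit variables are drawn independently per patient and
#' surgeon-unit variables once per surgeon (constant within surgeon), each
#' from its own seeded RNG substream.  Two volume summaries are derived from
#' the realised caseloads: `annual_volume` (patient-weighted caseload
#' quartile bands) and `high_volume` (caseload at or above its 83rd
#' percentile, the empirical high-volume surgeon rule).
#'
#' @param spec a [cohort_spec()].
#' @return data frame with `patient_id`, `surgeon_id`, `caseload`, derived
#'   volume variables, and one column per specified variable.
#' @examples
#' spec <- default_cohort_spec(n_patients = 500, n_surgeons = 90, seed = 1)
#' cohort <- generate_covariates(spec)
#' table(cohort$tumor_size_cm)
#' @export
generate_covariates <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  ns <- spec$n_surgeons

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  set.seed(stream_seed(spec$seed, "surgeon-assignment"))
  w <- stats::rgeom(ns, prob = 1 / spec$caseload_shape) + 1
  surgeon_id <- sample.int(ns, n, replace = TRUE, prob = w)
  caseload <- tabulate(surgeon_id, nbins = ns)[surgeon_id]

  out <- data.frame(patient_id = seq_len(n), surgeon_id = surgeon_id,
                    caseload = caseload)
  for (v in spec$variable_specs) {
    set.seed(stream_seed(spec$seed, paste0("var:", v$name)))
    if (v$unit == "patient") {
      out[[v$name]] <- sample(v$levels, n, replace = TRUE, prob = v$probs)
    } else {
      per_surgeon <- sample(v$levels, ns, replace = TRUE, prob = v$probs)
      out[[v$name]] <- per_surgeon[surgeon_id]
    }
  }
  # patient-weighted caseload quartiles and the 83rd-percentile rule
  qs <- stats::quantile(caseload, c(0.25, 0.5, 0.75), type = 1)
  out$annual_volume <- c("Bottom 25%", "2nd 25%", "3rd 25%", "Top 25%")[
    1L + (caseload > qs[1]) + (caseload > qs[2]) + (caseload > qs[3])]
  hv <- stats::quantile(tabulate(surgeon_id, nbins = ns)[
    tabulate(surgeon_id, nbins = ns) > 0], 0.83, type = 1)
  out$high_volume <- ifelse(caseload >= hv, "Yes", "No")
  out
}

#' Planted Boolean outcome rules
#'
#' The generative inverse of the logic-regression model: outcome
#' probabilities are
#' \eqn{\mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j L_j)} where each
#' \eqn{L_j} is a Boolean expression over encoded binary predictors.
#'
#' @param intercept log-odds intercept \eqn{\beta_0}.
#' @param rules list of [planted_rule()] entries.
#' @return a `planted_rules` object.
#' @export
planted_rules <- function(intercept, rules = list()) {
  for (r in rules) stopifnot(inherits(r, "planted_rule"))
  structure(list(intercept = as.numeric(intercept), rules = rules),
            class = "planted_rules")
}

#' @rdname planted_rules
#' @param expr and/or/not expression string over encoded predictor names
#'   (see [parse_tree()]).
#' @param beta log-odds coefficient of the rule.
#' @export
planted_rule <- function(expr, beta) {
  structure(list(expr = expr, beta = as.numeric(beta)),
            class = "planted_rule")
}

# Resolve rule expressions against a design's column names; errors on
# predictors the design does not have.
rule_trees <- function(rulespec, X) {
  nms <- colnames(design_matrix(X))
  lapply(rulespec$rules, function(r)
    tryCatch(parse_tree(r$expr, names = nms),
             error = function(e) stop("schema error: ", conditionMessage(e))))
}

# Linear predictor of a planted-rule model on a design.
rule_eta <- function(rulespec, X) {
  Xm <- design_matrix(X)
  eta <- rep(rulespec$intercept, nrow(Xm))
  trees <- rule_trees(rulespec, Xm)
  for (j in seq_along(trees))
    eta <- eta + rulespec$rules[[j]]$beta * eval_tree_columns(trees[[j]], Xm)
  eta
}

#' Plant a binary outcome from Boolean rules
#'
#' Draws \eqn{Y \sim \mathrm{Bernoulli}(p)} with
#' \eqn{p = \mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j L_j)} per row.
#'
#' @param design `binary_design` or 0/1 predictor matrix with column names.
#' @param rulespec a [planted_rules()] object.
#' @param seed integer seed.
#' @return integer 0/1 outcome vector.
#' @export
plant_outcome <- function(design, rulespec, seed) {
  p <- stats::plogis(rule_eta(rulespec, design))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::rbinom(length(p), 1L, p)
}

#' Analytic outcome rate of a planted-rule model on a design
#'
#' Mean of the per-row inverse-logit probabilities — the expectation of the
#' empirical outcome rate conditional on the covariates.
#'
#' @inheritParams plant_outcome
#' @return expected outcome rate in (0, 1).
#' @export
expected_rate <- function(design, rulespec) {
  mean(stats::plogis(rule_eta(rulespec, design)))
}

#' Calibrate the rule intercept to a target outcome rate
#'
#' Solves for \eqn{\beta_0} so that [expected_rate()] equals `target` on the
#' given design, holding the rule coefficients fixed.
#'
#' @param design `binary_design` or 0/1 matrix.
#' @param rulespec a [planted_rules()] object (its intercept is ignored).
#' @param target target outcome rate in (0, 1).
#' @return the calibrated `planted_rules` object.
#' @export
calibrate_intercept <- function(design, rulespec, target) {
  stopifnot(target > 0, target < 1)
  f <- function(b0) {
    rulespec$intercept <- b0
    expected_rate(design, rulespec) - target
  }
  rulespec$intercept <- stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
  rulespec
}

#' Default planted rules for the two treatment endpoints
#'
#' `default_pn_rules()` drives the partial-nephrectomy endpoint: a strong
#' tumor-size rule (odds ratio 5.9 for tumors <= 4 cm) and a
#' practice-environment rule (odds ratio 0.30 for surgeons lacking major
#' academic affiliation or an HMO/hospital/medical-school practice setting).
#' `default_lrn_rules()` drives laparoscopy use among radical nephrectomies:
#' major academic affiliation (odds ratio 2.12); large tumor, early
#' graduation, or solo practice (odds ratio 0.38); and low-volume non-NCI,
#' rural, or early-graduation-with-affiliation surgeons (odds ratio 0.29).
#' Intercepts are placeholders to be set by [calibrate_intercept()] against
#' the target base rates (15.2% partial nephrectomy; 20.6% laparoscopy
#' among radical nephrectomy).
#'
#' @return a `planted_rules` object.
#' @export
default_pn_rules <- function() {
  planted_rules(intercept = -2, rules = list(
    planted_rule("tumor_size_cm_le4", log(5.9)),
    planted_rule(paste0("(not academic_affiliation_Major or ",
                        "not (practice_size_HMO_or_hospital_based or ",
                        "practice_size_Medical_school))"),
                 log(0.30))))
}

#' @rdname default_pn_rules
#' @export
default_lrn_rules <- function() {
  grad_le_1980 <- paste0("(graduation_year_lt1960 or ",
                         "(graduation_year_1961_1970 or graduation_year_1971_1980))")
  planted_rules(intercept = -1.5, rules = list(
    planted_rule("academic_affiliation_Major", log(2.12)),
    planted_rule(paste0("(tumor_size_cm_gt4 or (", grad_le_1980,
                        " or practice_size_Solo_or_two_person))"),
                 log(0.38)),
    planted_rule(paste0("((not high_volume_Yes and not nci_center_Yes) or ",
                        "(rural_urban_Rural or (", grad_le_1980,
                        " and (academic_affiliation_Minor or ",
                        "academic_affiliation_Major))))"),
                 log(0.29))))
}

#' Simulate a full synthetic study
#'
#' Generates covariates, encodes them with the default schema, calibrates
#' the planted rule intercepts to the target base rates (partial
#' nephrectomy 15.2% overall; laparoscopy 20.6% among radical
#' nephrectomies), plants both endpoints, and labels each patient with one
#' of the four procedures (LPN/LRN/OPN/ORN; laparoscopy among
#' partial-nephrectomy patients is assigned at its marginal rate 427/1807,
#' used only for descriptive tables).
#'
#' @param spec a [cohort_spec()]; default [default_cohort_spec()].
#' @param pn_rules,lrn_rules planted rule sets (defaults
#'   [default_pn_rules()], [default_lrn_rules()]).
#' @param pn_rate,lrn_rate target base rates.
#' @param seed seed for the outcome draws (the covariate seed lives in
#'   `spec`).
#' @return list with `cohort` (covariates + `partial_nephrectomy`,
#'   `laparoscopy`, `procedure`), `design` (full-cohort `binary_design`
#'   with the partial-nephrectomy outcome), `design_rn` (radical-nephrectomy
#'   subset with the laparoscopy outcome), and the calibrated rule sets.
#' @export
simulate_study <- function(spec = default_cohort_spec(),
                           pn_rules = default_pn_rules(),
                           lrn_rules = default_lrn_rules(),
                           pn_rate = 1807 / 11918, lrn_rate = 2082 / 10111,
                           seed = 1) {
  cohort <- generate_covariates(spec)
  design <- encode(cohort, build_default_schema())

  pn_rules <- calibrate_intercept(design, pn_rules, pn_rate)
  pn <- plant_outcome(design, pn_rules, seed = stream_seed(seed, "pn"))
  cohort$partial_nephrectomy <- pn
  design$y <- pn

  rn <- which(pn == 0L)
  design_rn <- design
  design_rn$X <- design$X[rn, , drop = FALSE]
  design_rn$row_index <- design$row_index[rn]
  lrn_rules <- calibrate_intercept(design_rn, lrn_rules, lrn_rate)
  lap_rn <- plant_outcome(design_rn, lrn_rules, seed = stream_seed(seed, "lrn"))
  design_rn$y <- lap_rn

  old <- get0(".Random.seed", envir = globalenv())
  set.seed(stream_seed(seed, "lpn-split"))
  lap <- integer(nrow(cohort))
  lap[rn] <- lap_rn
  lap[pn == 1L] <- stats::rbinom(sum(pn), 1L, 427 / 1807)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  cohort$laparoscopy <- lap
  cohort$procedure <- ifelse(pn == 1L, ifelse(lap == 1L, "LPN", "OPN"),
                             ifelse(lap == 1L, "LRN", "ORN"))

  list(cohort = cohort, design = design, design_rn = design_rn,
       pn_rules = pn_rules, lrn_rules = lrn_rules)
}

#' Read/write a synthetic cohort as CSV
#'
#' @param cohort data frame from [generate_covariates()].
#' @param path CSV path (header row, one row per patient).
#' @return `read_cohort()` returns the data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read/write planted rules as YAML
#'
#' @param rulespec a `planted_rules` object.
#' @param path file path.
#' @export
write_rules <- function(rulespec, path) {
  yaml::write_yaml(list(intercept = rulespec$intercept,
                        rules = lapply(rulespec$rules, function(r)
                          list(expr = r$expr, beta = r$beta))), path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  planted_rules(raw$intercept,
                lapply(raw$rules, function(r) planted_rule(r$expr, r$beta)))
}
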