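# Synthetic cohort generator: marginals, nesting, determinism, planted
# outcomes, and the embedded printed-table fixtures.

simple_spec <- function(n, probs, seed = 1, levels = letters[seq_along(probs)],
                        unit = "patient") {
  cohort_spec(n, max(2, n %/% 10), list(
    cohort_variable("v", "categorical", levels, probs, unit = unit)),
    seed = seed)
}

test_that("empirical marginals stay within three Monte-Carlo SEs", {
  # one binary variable at p = 0.5, n = 10,000
  cohort <- generate_covariates(simple_spec(10000, c(0.5, 0.5), seed = 7))
  expect_gte(mean(cohort$v == "a"), 0.485)
  expect_lte(mean(cohort$v == "a"), 0.515)

  # the printed tumor-size margin: 5188 of 11589 tumors at <= 4 cm
  p <- 5188 / 11589
  spec <- cohort_spec(11589, 2000, list(
    cohort_variable("tumor_size_cm", "continuous", c("<=4", ">4"),
                    c(p, 1 - p))), seed = 9)
  cohort <- generate_covariates(spec)
  se <- sqrt(p * (1 - p) / 11589)
  expect_lt(abs(mean(cohort$tumor_size_cm == "<=4") - p), 3 * se)

  # degenerate single level
  cohort <- generate_covariates(simple_spec(50, 1, seed = 3, levels = "only"))
  expect_true(all(cohort$v == "only"))
})

test_that("invalid marginals are schema errors", {
  expect_error(simple_spec(100, c(0.6, 0.6)), "schema error")
  expect_error(simple_spec(100, c(-0.2, 1.2)), "schema error")
  expect_error(cohort_spec(10, 20, list(), seed = 1))
})

test_that("identical spec and seed give byte-identical cohorts", {
  spec <- default_cohort_spec(n_patients = 800, n_surgeons = 140, seed = 33)
  expect_identical(generate_covariates(spec), generate_covariates(spec))
  spec2 <- default_cohort_spec(n_patients = 800, n_surgeons = 140, seed = 34)
  expect_false(identical(generate_covariates(spec),
                         generate_covariates(spec2)))
})

test_that("per-variable RNG streams: adding a variable leaves others intact", {
  base <- default_cohort_spec(n_patients = 500, n_surgeons = 80, seed = 5)
  extended <- base
  extended$variable_specs <- c(extended$variable_specs, list(
    extra = cohort_variable("extra", "categorical", c("u", "v"), c(0.5, 0.5))))
  a <- generate_covariates(base)
  b <- generate_covariates(extended)
  expect_identical(a$tumor_size_cm, b$tumor_size_cm)
  expect_identical(a$academic_affiliation, b$academic_affiliation)
  expect_identical(a$surgeon_id, b$surgeon_id)
})

test_that("surgeon-level variables are constant within surgeon", {
  cohort <- generate_covariates(default_cohort_spec(2000, 350, seed = 13))
  for (v in c("academic_affiliation", "practice_size", "graduation_year",
              "rural_urban", "nci_center", "high_volume")) {
    per <- tapply(cohort[[v]], cohort$surgeon_id,
                  function(x) length(unique(x)))
    expect_true(all(per == 1), label = paste("constant within surgeon:", v))
  }
  # skewed caseloads: many low-volume providers
  loads <- table(cohort$surgeon_id)
  expect_lt(median(loads), mean(loads))
})

test_that("planted outcomes match their analytic rates", {
  set.seed(77)
  X <- matrix(rbinom(20000 * 3, 1, c(0.45, 0.5, 0.5)), 20000, 3, byrow = TRUE)
  colnames(X) <- c("A", "B", "C")
  d <- structure(list(X = X), class = "binary_design")

  # intercept 0, no rules: rate ~ 0.5
  y0 <- plant_outcome(d, planted_rules(0), seed = 1)
  expect_lt(abs(mean(y0) - 0.5), 3 * sqrt(0.25 / 20000))

  # closed-form mixture: 0.55 * logit^-1(-2) + 0.45 * logit^-1(-2 + log 5.9)
  rs <- planted_rules(-2, list(planted_rule("A", log(5.9))))
  pA <- mean(X[, "A"])
  mix <- (1 - pA) * plogis(-2) + pA * plogis(-2 + log(5.9))
  expect_equal(expected_rate(d, rs), mix, tolerance = 1e-12)
  y1 <- plant_outcome(d, rs, seed = 2)
  expect_lt(abs(mean(y1) - mix), 3 * sqrt(mix * (1 - mix) / 20000))

  # a zero-coefficient rule changes nothing under the same seed
  rs0 <- planted_rules(-2, list(planted_rule("A", 0)))
  expect_identical(plant_outcome(d, rs0, seed = 5),
                   plant_outcome(d, planted_rules(-2), seed = 5))

  # rules must reference existing predictors
  bad <- planted_rules(0, list(planted_rule("nope", 1)))
  expect_error(plant_outcome(d, bad, seed = 1), "schema error")
})

test_that("calibrated intercepts hit the target base rates", {
  sim <- suppressWarnings(
    simulate_study(default_cohort_spec(4000, 700, seed = 2), seed = 11))
  expect_equal(expected_rate(sim$design, sim$pn_rules), 1807 / 11918,
               tolerance = 1e-8)
  rate <- mean(sim$cohort$partial_nephrectomy)
  expect_lt(abs(rate - 1807 / 11918), 3 * sqrt(0.152 * 0.848 / 4000))
  lap_rate <- mean(sim$design_rn$y)
  expect_lt(abs(lap_rate - 2082 / 10111),
            3 * sqrt(0.206 * 0.794 / length(sim$design_rn$y)))
  expect_setequal(unique(sim$cohort$procedure), c("LPN", "LRN", "OPN", "ORN"))
})

test_that("fixture tables reproduce the printed cells and totals", {
  fx <- fixtures()
  t1 <- fx$table1
  expect_equal(t1$lpn[t1$variable == "tumor_size_cm" & t1$level == "<=4"], 352)
  t2 <- fx$table2
  expect_equal(t2$orn[t2$variable == "practice_size" &
                        t2$level == "Solo or two-person"], 2601)
  expect_identical(unname(fx$procedure_totals), c(427L, 2082L, 1380L, 8029L))
  expect_equal(sum(fx$procedure_totals), 11918)
  expect_equal(fx$n_total, 11918L)
  # every fixture row's procedure counts sum to its printed total
  for (t in list(t1, t2))
    expect_identical(t$lpn + t$lrn + t$opn + t$orn, t$total)
  # count matrix accessor
  m <- fixture_counts(fx$table1, "tumor_size_cm")
  expect_identical(m["<=4", "lpn"], 352L)
  expect_error(fixture_counts(fx$table1, "nope"), "no fixture variable")
})

test_that("cohort and rule files round-trip through disk", {
  spec <- default_cohort_spec(200, 40, seed = 21)
  cohort <- generate_covariates(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back$tumor_size_cm, cohort$tumor_size_cm)
  expect_equal(back$surgeon_id, cohort$surgeon_id)

  rs <- default_lrn_rules()
  rpath <- withr::local_tempfile(fileext = ".yaml")
  write_rules(rs, rpath)
  rs2 <- read_rules(rpath)
  expect_equal(rs2$intercept, rs$intercept)
  expect_equal(vapply(rs2$rules, `[[`, character(1), "expr"),
               vapply(rs$rules, `[[`, character(1), "expr"))
})
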