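# Binary recoding: default schema, threshold bands, indicator sets,
# provenance, missing-data policy.

test_that("default schema encodes the clinical cutpoints", {
  sch <- build_default_schema()
  cohort <- data.frame(
    tumor_size_cm = c(3.2, 4.0, 4.1, 9, 1.5),
    age_at_surgery = c(65, 72, 78, 84, 91),
    charlson_score = c(0, 1, 2, 5, 1),
    graduation_year = c(1955, 1965, 1975, 1990, 1999),
    surgeon_age = c(39, 45, 55, 60, 71),
    practice_size = c("Group practice", "Solo or two-person",
                      "HMO or hospital-based", "Medical school", "weird"),
    academic_affiliation = c("None", "Minor", "Major", "None", "Minor"),
    married = c("Yes", "No", "Yes", "No", "Yes"),
    race_ethnicity = c("Caucasian", "Hispanic", "African-American", "Asian",
                       "Caucasian"),
    rural_urban = c("Urban", "Rural", "Urban", "Urban", "Rural"),
    nci_center = c("No", "Yes", "No", "No", "Yes"),
    high_volume = c("No", "No", "Yes", "Yes", "No"))
  d <- encode(cohort, sch)
  X <- d$X
  # 4 cm threshold: 3.2, 4.0 and 1.5 are <=4; 4.1 and 9 are not
  expect_identical(unname(X[, "tumor_size_cm_le4"]), c(1L, 1L, 0L, 0L, 1L))
  # graduation 1975 falls in the 1971-1980 band, and only there
  grad_cols <- grep("^graduation_year_", colnames(X), value = TRUE)
  expect_identical(unname(X[3, grad_cols]),
                   as.integer(grad_cols == "graduation_year_1971_1980"))
  # Charlson 5 saturates the >=2 band
  expect_identical(unname(X[4, "charlson_score_ge2"]), 1L)
  # five-year age bands partition every row
  age_cols <- grep("^age_at_surgery_", colnames(X), value = TRUE)
  expect_equal(length(age_cols), 5)
  expect_identical(unname(rowSums(X[, age_cols])), rep(1, 5))
  # unseen race level routed to the "other" bucket, as is practice "weird"
  expect_identical(unname(X[4, "race_ethnicity_Other_or_Unknown"]), 1L)
  expect_identical(unname(X[5, "practice_size_Other_unclassified"]), 1L)
})

test_that("indicator sets and threshold series are one-hot partitions", {
  set.seed(121)
  cohort <- data.frame(
    color = sample(c("red", "green", "blue"), 200, replace = TRUE),
    score = runif(200, 0, 10))
  sch <- coding_schema(
    schema_variable("color", "indicator-set",
                    levels = c("red", "green", "blue")),
    schema_variable("score", "threshold-series",
                    levels = c("low", "mid", "high"), cutpoints = c(3, 7)))
  d <- encode(cohort, sch)
  color_cols <- grep("^color_", colnames(d$X))
  score_cols <- grep("^score_", colnames(d$X))
  expect_identical(unname(rowSums(d$X[, color_cols])), rep(1, 200))
  expect_identical(unname(rowSums(d$X[, score_cols])), rep(1, 200))
  # encoding is row-order independent
  perm <- sample(200)
  d2 <- encode(cohort[perm, ], sch)
  expect_identical(d2$X, d$X[perm, ])
})

test_that("constant columns are dropped with a warning", {
  cohort <- data.frame(a = c("x", "x", "y"), b = c("u", "u", "u"))
  sch <- coding_schema(
    schema_variable("a", "indicator-set", levels = c("x", "y")),
    schema_variable("b", "indicator-set", levels = c("u", "v")))
  expect_warning(d <- encode(cohort, sch), "constant")
  expect_false(any(c("b_u", "b_v") %in% colnames(d$X)))
  expect_setequal(d$dropped_columns, c("b_u", "b_v"))
  # oracle: the dropped columns are exactly the zero-variance ones
  full <- c(b_u = 0, b_v = 0, a_x = var(c(1, 1, 0)), a_y = var(c(0, 0, 1)))
  expect_setequal(d$dropped_columns, names(full)[full == 0])
})

test_that("rows with missing modeled values are excluded with a message", {
  cohort <- data.frame(a = c("x", NA, "y", "y"), b = c(1, 2, NA, 4))
  sch <- coding_schema(
    schema_variable("a", "indicator-set", levels = c("x", "y")),
    schema_variable("b", "threshold-series", levels = c("lo", "hi"),
                    cutpoints = 2.5))
  expect_message(d <- encode(cohort, sch), "excluding 2 row")
  expect_equal(nrow(d$X), 2)
  expect_identical(d$row_index, c(1L, 4L))
})

test_that("unseen level without an other bucket is an error", {
  cohort <- data.frame(a = c("x", "z"))
  sch <- coding_schema(schema_variable("a", "indicator-set",
                                       levels = c("x", "y")))
  expect_error(encode(cohort, sch), "encoding error")
  expect_error(encode(data.frame(b = 1), sch), "lacks variable")
})

test_that("provenance reconstructs the raw category for every row", {
  set.seed(131)
  cohort <- data.frame(
    band = sample(c("a", "b", "c"), 150, replace = TRUE),
    flag = sample(c("Yes", "No"), 150, replace = TRUE))
  sch <- coding_schema(
    schema_variable("band", "indicator-set", levels = c("a", "b", "c")),
    schema_variable("flag", "indicator", levels = "Yes"))
  d <- encode(cohort, sch)
  expect_identical(decode_design(d, "band"), cohort$band)
  expect_identical(decode_design(d, "flag"),
                   ifelse(cohort$flag == "Yes", "Yes", "not Yes"))
  # encoding twice is idempotent
  expect_identical(encode(cohort, sch)$X, d$X)
})

test_that("schema YAML round-trips", {
  sch <- build_default_schema()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_schema(sch, path)
  sch2 <- read_schema(path)
  expect_equal(unclass(sch2), unclass(sch), ignore_attr = TRUE)
})

test_that("schema validation rejects malformed entries", {
  expect_error(schema_variable("x", "threshold-series", levels = c("a", "b"),
                               cutpoints = c(2, 1)), "strictly increasing")
  expect_error(schema_variable("x", "threshold-series", levels = c("a"),
                               cutpoints = 1), "band label")
  expect_error(coding_schema(
    schema_variable("x", "indicator", levels = "a"),
    schema_variable("x", "indicator", levels = "b")), "duplicate")
})
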