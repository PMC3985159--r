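# Printed cohort cross-tabulations embedded as exact count fixtures.
# Columns are the four mutually exclusive surgical procedures:
# LPN = laparoscopic partial nephrectomy, LRN = laparoscopic radical
# nephrectomy, OPN = open partial nephrectomy, ORN = open radical
# nephrectomy.  Each row stores the printed count and the printed
# one-decimal row percentage for every procedure, plus the printed
# chi-square P value for the variable block.

fixture_row <- function(variable, level, total,
                        lpn, lpn_pct, lrn, lrn_pct,
                        opn, opn_pct, orn, orn_pct, p_value) {
  data.frame(variable = variable, level = level, total = total,
             lpn = lpn, lpn_pct = lpn_pct, lrn = lrn, lrn_pct = lrn_pct,
             opn = opn, opn_pct = opn_pct, orn = orn, orn_pct = orn_pct,
             p_value = p_value, stringsAsFactors = FALSE)
}

#' Embedded patient/tumor and surgeon/practice cross-tabulation fixtures
#'
#' Exact printed counts (and printed one-decimal row percentages) of the
#' published distribution of 11,918 kidney-cancer surgeries over the four
#' procedure types, by patient/tumor characteristics (`table1`) and by
#' surgeon/practice-environment characteristics (`table2`).  These anchor
#' the test suite: every percentage is recomputable from the counts, and the
#' procedure totals row is (LPN 427, LRN 2082, OPN 1380, ORN 8029),
#' summing to 11,918.
#'
#' @return list with data frames `table1` and `table2` (columns `variable`,
#'   `level`, `total`, per-procedure counts `lpn`/`lrn`/`opn`/`orn` with
#'   printed percentages `*_pct`, and the printed `p_value`), plus
#'   `procedure_totals` (named count vector) and `n_total`.
#' @examples
#' fx <- fixtures()
#' subset(fx$table1, variable == "tumor_size_cm")
#' @export
fixtures <- function() {
  r <- fixture_row
  table1 <- rbind(
    r("age_at_surgery", "65-69", 3127, 131, 4.2, 530, 16.9, 431, 13.8, 2035, 65.1, 0.0001),
    r("age_at_surgery", "70-74", 3423, 122, 3.6, 536, 15.7, 426, 12.5, 2339, 68.3, 0.0001),
    r("age_at_surgery", "75-79", 3024,  98, 3.2, 579, 19.2, 354, 11.7, 1993, 65.9, 0.0001),
    r("age_at_surgery", "80-84", 1721,  59, 3.4, 300, 17.4, 139,  8.1, 1223, 71.1, 0.0001),
    r("age_at_surgery", ">=85",   623,  17, 2.7, 137, 22.0,  30,  4.8,  439, 70.5, 0.0001),
    r("race_ethnicity", "Caucasian",        9884, 344, 3.5, 1757, 17.8, 1158, 11.7, 6625, 67.0, 0.0001),
    r("race_ethnicity", "African-American",  878,  33, 3.8,  154, 17.5,  103, 11.7,  588, 67.0, 0.0001),
    r("race_ethnicity", "Hispanic",           719,  27, 3.8,   81, 11.3,   70,  9.7,  541, 75.2, 0.0001),
    r("race_ethnicity", "Other or Unknown",   437,  23, 5.3,   90, 20.6,   49, 11.2,  275, 62.9, 0.0001),
    r("gender", "Male",   6882, 274, 3.9, 1134, 16.5, 850, 12.4, 4624, 67.2, 0.0001),
    r("gender", "Female", 5036, 153, 3.0,  948, 18.8, 530, 10.5, 3405, 67.6, 0.0001),
    r("married", "Yes", 7499, 294, 3.9, 1274, 17.0, 901, 12.0, 5030, 67.1, 0.005),
    r("married", "No",  4419, 133, 3.0,  808, 18.3, 479, 10.8, 2999, 67.9, 0.005),
    r("socioeconomic_status", "Low",          3808, 134, 3.5, 603, 15.8, 424, 11.1, 2647, 69.5, 0.0001),
    r("socioeconomic_status", "Intermediate", 3899, 135, 3.5, 633, 16.2, 386,  9.9, 2745, 70.4, 0.0001),
    r("socioeconomic_status", "High",         4196, 158, 3.8, 846, 20.2, 568, 13.5, 2624, 62.5, 0.0001),
    r("charlson_score", "0",   6842, 241, 3.5, 1186, 17.3, 794, 11.6, 4621, 67.5, 0.38),
    r("charlson_score", "1",   2847, 104, 3.7,  512, 18.0, 313, 11.0, 1918, 67.4, 0.38),
    r("charlson_score", ">=2", 1904,  74, 3.9,  345, 18.1, 246, 12.9, 1239, 65.1, 0.38),
    r("tumor_size_cm", "<=4", 5188, 352, 6.8,  949, 18.3, 1035, 20.0, 2852, 54.9, 0.0001),
    r("tumor_size_cm", ">4",  6401,  51, 0.8, 1101, 17.2,  286,  4.5, 4963, 77.5, 0.0001),
    r("tumor_histology", "Clear cell", 10000, 301, 3.0, 1682, 16.8, 1042, 10.4, 6975, 69.8, 0.0001),
    r("tumor_histology", "Papillary",    888,  77, 8.7,  200, 22.5,  170, 19.1,  441, 49.7, 0.0001),
    r("tumor_histology", "Chromophobe",  391,  24, 6.1,  107, 27.4,   82, 21.0,  178, 45.5, 0.0001),
    r("tumor_histology", "Other",        639,  25, 3.9,   93, 14.6,   86, 13.5,  435, 68.1, 0.0001))

  table2 <- rbind(
    r("surgeon_age", "<40",   2553, 147, 5.8, 774, 30.3, 271, 10.6, 1361, 53.3, 0.0001),
    r("surgeon_age", "40-49", 4034, 170, 4.2, 728, 18.1, 440, 10.9, 2696, 66.8, 0.0001),
    r("surgeon_age", "50-59", 3710,  85, 2.3, 427, 11.5, 458, 12.4, 2740, 73.9, 0.0001),
    r("surgeon_age", ">=60",  1621,  25, 1.5, 153,  9.4, 211, 13.0, 1232, 76.0, 0.0001),
    r("surgeon_gender", "Male",   11684, 419, 3.6, 2036, 17.4, 1364, 11.7, 7865, 67.3, 0.0001),
    r("surgeon_gender", "Female",   234,   8, 3.4,   46, 19.7,   16,  6.8,  164, 70.1, 0.0001),
    r("annual_volume", "Bottom 25%", 2279,  34, 1.5, 209,  9.2, 230, 10.1, 1806, 79.3, 0.0001),
    r("annual_volume", "2nd 25%",    3474,  77, 2.2, 458, 13.2, 370, 10.7, 2569, 73.9, 0.0001),
    r("annual_volume", "3rd 25%",    3141, 107, 3.4, 519, 16.5, 320, 10.2, 2195, 69.9, 0.0001),
    r("annual_volume", "Top 25%",    3024, 209, 6.9, 896, 29.6, 460, 15.2, 1459, 48.3, 0.0001),
    r("graduation_year", "<1960",     346,   2, 0.6,   9,  2.6,  48, 13.9,  287, 82.9, 0.0001),
    r("graduation_year", "1961-1970", 2488,  25, 1.0, 176,  7.1, 301, 12.1, 1986, 79.8, 0.0001),
    r("graduation_year", "1971-1980", 3568,  89, 2.5, 437, 12.3, 403, 11.3, 2639, 73.9, 0.0001),
    r("graduation_year", "1981-1990", 3705, 166, 4.5, 738, 19.9, 431, 11.6, 2370, 63.9, 0.0001),
    r("graduation_year", ">=1991",    1811, 145, 8.0, 722, 39.9, 197, 10.9,  747, 41.3, 0.0001),
    r("practice_size", "Solo or two-person",   3200,  36, 1.1,  284,  8.9, 279,  8.7, 2601, 81.3, 0.0001),
    r("practice_size", "Group practice",       6619, 274, 4.1, 1368, 20.7, 709, 10.7, 4268, 64.5, 0.0001),
    r("practice_size", "HMO or hospital-based",  631,  29, 4.6,  100, 15.9, 141, 22.4,  361, 57.2, 0.0001),
    r("practice_size", "Medical school",         484,  34, 7.0,   98, 20.3, 125, 25.8,  227, 46.9, 0.0001),
    r("practice_size", "Other/unclassified",     984,  54, 5.5,  232, 23.6, 126, 12.8,  572, 58.1, 0.0001),
    r("academic_affiliation", "None",  4195,  88, 2.1, 660, 15.7, 385,  9.2, 3062, 72.9, 0.0001),
    r("academic_affiliation", "Minor", 4408, 127, 2.9, 740, 16.8, 420,  9.5, 3121, 70.8, 0.0001),
    r("academic_affiliation", "Major", 3201, 207, 6.5, 668, 20.9, 561, 17.5, 1765, 55.1, 0.0001),
    r("rural_urban", "Urban", 11093, 412, 3.7, 1992, 17.9, 1318, 11.9, 7371, 66.5, 0.0001),
    r("rural_urban", "Rural",   823,  15, 1.8,   89, 10.8,   61,  7.4,  658, 79.9, 0.0001),
    r("nci_center", "No",  10793, 322, 2.9, 1861, 17.2, 1125, 10.4, 7485, 69.4, 0.0001),
    r("nci_center", "Yes",  1096, 102, 9.3,  219, 19.9,  252, 22.9,  523, 47.7, 0.0001))

  list(table1 = table1, table2 = table2,
       procedure_totals = c(lpn = 427L, lrn = 2082L, opn = 1380L, orn = 8029L),
       n_total = 11918L)
}

#' Counts for one fixture variable as a levels x procedures matrix
#'
#' @param table one of the data frames returned by [fixtures()].
#' @param variable variable name (e.g. `"tumor_size_cm"`).
#' @return integer matrix with level row names and columns
#'   `lpn`, `lrn`, `opn`, `orn`.
#' @export
fixture_counts <- function(table, variable) {
  rows <- table[table$variable == variable, , drop = FALSE]
  if (!nrow(rows)) stop("no fixture variable named '", variable, "'")
  m <- as.matrix(rows[, c("lpn", "lrn", "opn", "orn")])
  rownames(m) <- rows$level
  storage.mode(m) <- "integer"
  m
}

#' Write the fixture tables as CSV files
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_fixtures <- function(dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- fixtures()
  paths <- file.path(dir, c("table1_patient_tumor.csv",
                            "table2_surgeon_practice.csv"))
  utils::write.csv(fx$table1, paths[1], row.names = FALSE)
  utils::write.csv(fx$table2, paths[2], row.names = FALSE)
  invisible(paths)
}
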