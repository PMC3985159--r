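# The printed source tables carry 23 cells whose final percentage decimal
# disagrees with their own count arithmetic by exactly one unit in the last
# place (print rounding inconsistencies; every row's counts do sum to its
# printed total).  They are frozen here so the fixture-integrity sweep can
# demand exact agreement everywhere else and exactly-0.1 disagreement here.
fixture_pct_errata <- function() {
  e <- function(tab, variable, level, proc)
    data.frame(tab = tab, variable = variable, level = level, proc = proc)
  rbind(
    e("table1", "age_at_surgery", "70-74", "opn"),
    e("table1", "age_at_surgery", "75-79", "lrn"),
    e("table1", "gender", "Male", "lpn"),
    e("table1", "tumor_size_cm", "<=4", "opn"),
    e("table1", "tumor_size_cm", "<=4", "orn"),
    e("table2", "surgeon_age", "40-49", "lrn"),
    e("table2", "surgeon_age", "50-59", "opn"),
    e("table2", "annual_volume", "Bottom 25%", "orn"),
    e("table2", "annual_volume", "Top 25%", "orn"),
    e("table2", "graduation_year", "1971-1980", "lrn"),
    e("table2", "graduation_year", "1971-1980", "orn"),
    e("table2", "graduation_year", "1981-1990", "orn"),
    e("table2", "graduation_year", ">=1991", "orn"),
    e("table2", "practice_size", "HMO or hospital-based", "lrn"),
    e("table2", "practice_size", "HMO or hospital-based", "opn"),
    e("table2", "practice_size", "Medical school", "lrn"),
    e("table2", "academic_affiliation", "None", "orn"),
    e("table2", "rural_urban", "Urban", "lrn"),
    e("table2", "rural_urban", "Urban", "orn"),
    e("table2", "rural_urban", "Rural", "orn"),
    e("table2", "nci_center", "No", "lpn"),
    e("table2", "nci_center", "Yes", "lrn"),
    e("table2", "nci_center", "Yes", "opn"))
}
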