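#!/usr/bin/env Rscript

# Step 2: descriptive tables and chi-square screens.
#
# Exports the embedded printed cross-tabulations (the study-scale anchors)
# and recomputes the same descriptive layout on the synthetic cohort:
# each covariate cross-tabulated against the four procedures
# (LPN/LRN/OPN/ORN) with row percentages and a Pearson chi-square screen.

library(boolereg)

dir.create("results", showWarnings = FALSE)
export_fixtures("results")

spec <- default_cohort_spec(n_patients = 3000, n_surgeons = 550,
                            seed = 20140327)
sim <- suppressWarnings(simulate_study(spec, seed = 1))
cohort <- sim$cohort

vars <- c("age_at_surgery", "race_ethnicity", "gender", "married",
          "socioeconomic_status", "charlson_score", "tumor_size_cm",
          "tumor_histology", "surgeon_age", "graduation_year",
          "practice_size", "academic_affiliation", "rural_urban",
          "nci_center", "annual_volume", "high_volume")
proc_levels <- c("LPN", "LRN", "OPN", "ORN")

rows <- list()
for (v in vars) {
  ct <- crosstab(cohort, v, "procedure", col_levels = proc_levels)
  sc <- suppressWarnings(chisq_screen(ct))
  for (lv in rownames(ct$counts)) {
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = lv, total = unname(ct$row_totals[lv]),
      lpn = ct$counts[lv, "LPN"], lpn_pct = ct$pct[lv, "LPN"],
      lrn = ct$counts[lv, "LRN"], lrn_pct = ct$pct[lv, "LRN"],
      opn = ct$counts[lv, "OPN"], opn_pct = ct$pct[lv, "OPN"],
      orn = ct$counts[lv, "ORN"], orn_pct = ct$pct[lv, "ORN"],
      chisq_p = signif(sc$p_value, 3))
  }
}
desc <- do.call(rbind, rows)
write.csv(desc, "results/synthetic_descriptives.csv", row.names = FALSE)

cat("Chi-square screens on the synthetic cohort (planted structure):\n")
shown <- unique(desc[, c("variable", "chisq_p")])
print(shown, row.names = FALSE)
cat("\nVariables driving the planted rules (tumor size, affiliation,",
    "practice, graduation year, volume) should generally screen",
    "significant at this scale; variables outside the rules, and",
    "weak-marginal rule members, should not.\n")
cat("wrote results/synthetic_descriptives.csv and fixture CSVs\n")
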