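#!/usr/bin/env Rscript

# Step 4: choose model complexity by repeated stratified cross-validation.
#
# Runs a reduced complexity grid for the partial-nephrectomy endpoint on
# the synthetic cohort: held-out binomial deviance per (trees, leaf-budget)
# cell, averaged over stratified folds and repeated splits; the cell with
# the smallest grand-mean deviance is selected (parsimony on ties), the
# representative repeat is the one closest to the grand mean, and the final
# model is refit on the full data at the selected complexity.  The grid
# here is desk-scale (2 x 3 cells, 3 folds, 2 repeats); the full-scale
# protocol (1-4 trees, 1-15 leaves, tenfold, 15 repeats) uses the same
# functions with larger arguments.

library(boolereg)

dir.create("results", showWarnings = FALSE)

spec <- default_cohort_spec(n_patients = 3000, n_surgeons = 550,
                            seed = 20140327)
sim <- suppressWarnings(simulate_study(spec, seed = 1))
sched <- anneal_schedule(end = 0.5, n_iter = 1500)

grid <- cv_grid(sim$design, tree_grid = 1:2, leaf_grid = c(1, 2, 4),
                k = 3, n_repeats = 2, schedule = sched, seed = 42)
write_cv_grid(grid, "results/cv_grid.csv")

sel <- select_model(grid, sim$design, schedule = sched, seed = 77,
                    restarts = 3)
print(sel)

gm <- sel$grand_means
gm$test_deviance <- round(gm$test_deviance, 4)
write.csv(gm, "results/cv_grand_means.csv", row.names = FALSE)
final_report <- render_model_report(sel$model, sim$design, sim$design$y)
write_model_report(final_report, "results/cv_selected_model.csv")

cat(sprintf(paste0(
  "\nSelected: %d tree(s), leaf budget %d.\n",
  "The planted truth uses two rules, but the second (the practice-\n",
  "environment clause, odds ratio 0.30 in a minority subgroup) buys only\n",
  "~0.006 held-out deviance per observation at n = 3,000 — below the\n",
  "annealing noise of these desk-scale schedules — so parsimonious\n",
  "one-tree selections are expected here.  The two-tree selection\n",
  "behaviour is exercised where it is identifiable: two strong\n",
  "opposite-signed rules (see the acceptance checks), which no single\n",
  "tree can absorb.\n"),
  sel$selected$p_trees, sel$selected$leaf_budget))
cat("wrote results/cv_grid.csv, cv_grand_means.csv, cv_selected_model.csv\n")
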