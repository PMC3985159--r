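---
title: "Logic regression for treatment-delivery cohorts: model, search, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logic regression for treatment-delivery cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolereg)
```

## The problem

Whether a patient with early-stage kidney cancer receives an innovative
operation — a kidney-sparing partial nephrectomy, or a laparoscopic rather
than open radical nephrectomy — depends not only on the tumor but on who
operates and where: the surgeon's training era, caseload, academic
affiliation, practice structure, rurality, cancer-center ties.  Ordinary
logistic regression measures each of these as a *main effect*; it discovers
an interaction only if the analyst writes it into the model first.  The
question this package addresses is the opposite one: *search* for the
combinations — Boolean and/or/not clauses over patient, surgeon, and
practice-environment indicators — that best separate users from non-users
of a treatment.

## The model

Let \(X_1,\dots,X_k\) be binary (0/1) predictors and \(Y\) a binary
endpoint.  A **logic tree** \(L\) is a full binary tree whose leaves are
(possibly complemented) predictors and whose internal nodes — "knots" —
are AND/OR operators; \(L = 1\) when the expression is true.  A logic
regression model with \(p\) trees is the logistic model

\[
\operatorname{logit} P(Y = 1 \mid L_1,\dots,L_p)
  = \beta_0 + \beta_1 L_1 + \cdots + \beta_p L_p ,
\]

fitted by maximum likelihood and scored by the **binomial deviance**
\(-2\sum_i [\,y_i \log \hat p_i + (1-y_i)\log(1-\hat p_i)\,]\).  What
distinguishes this from logistic regression with fixed covariates is that
the trees \(L_j\) are *searched over* jointly with the estimation of the
\(\beta_j\).  Complements live on leaves only; by De Morgan's laws this
loses no generality, and a tree with a negative coefficient is the same
model as its complement with the sign flipped (`complement_tree()`,
`recovered_rule()`).

## The search

The space of Boolean expressions is far too large to enumerate, so the
trees are perturbed by simulated annealing (`anneal_fit()`).  At each step
one tree is chosen uniformly and one of six moves is proposed at random
among those applicable: alternate a leaf, alternate an operator,
grow/prune a branch, split/delete a leaf.  Every move has an inverse move,
so the chain can always retrace its steps.  All coefficients are refit at
every proposal — on the *collapsed* covariate-pattern table, which is
exact for binary covariates and reduces each refit to an IRLS on at most
\(2^p\) rows (a single-tree proposal is a closed-form 2×2 fit).  A proposal
improving the deviance is always accepted; a worsening one is accepted
with probability \(\exp(-\Delta/T)\) under a geometrically cooling
temperature \(T\).

Numerical choices worth stating:

* **Start temperature.** Unless given, it is auto-tuned from a burn-in
  random walk of 500 accepted-regardless proposals: the 90th percentile of
  the worsening score gaps seen along the walk is scaled so such a gap is
  initially accepted with probability about 0.9.  Probing a *walk* rather
  than the initial state is essential — the gaps that matter are the
  barriers between competing local modes (e.g. between a strong single
  leaf and the conjunction that extends it), and those are invisible from
  the starting tree.
* **End temperature and length.** The package default is a long
  conservative schedule (50,000 iterations, end temperature \(10^{-3}\)).
  The analyses and tests in this repository use shorter desk-scale
  schedules (typically 1,200–8,000 iterations, end temperature 0.5, with
  2–10 restarts); the best-so-far model is tracked throughout, so a warm
  late phase costs nothing and helps the chain keep exploring plateaus of
  score-equivalent trees.
* **Separation.** Rare Boolean combinations in small folds routinely
  separate the outcome.  Each fitted group log-odds is capped at ±15
  (probabilities pinned to about \(3\times10^{-7}\) from the boundary) and
  the model flagged, rather than failing; this keeps the chain alive and
  lets an exactly-determined outcome reach essentially zero deviance.  A
  slope can therefore reach ±30 when the two groups separate in opposite
  directions.
* **Degenerate columns.** A proposal whose tree evaluates to a constant,
  or duplicates another tree's column, is fitted with that column dropped
  and flagged — it simply scores as the smaller model.
* **Leaf budgets.** The budget is enforced *per tree* by default (the
  move proposer only offers growth while under budget); a total-leaves
  mode is available via `budget_mode = "total"`, under which cells with
  budget below the tree count are infeasible.

## Model-size selection

Complexity is two-dimensional: the number of trees \(p\) (1–4) and the
leaf budget (1–15).  Larger models always fit better in-sample, so the
size is chosen by repeated, stratified ten-fold cross-validation
(`cv_grid()`): folds preserve the outcome split to within one patient per
class; each cell's model is annealed on nine folds and scored on the
held-out fold; fold deviances are normalised per observation (so unequal
folds weigh fairly — the protocol does not specify this) and averaged, and
the whole procedure is repeated with fresh splits (15 by default).  The
cell with the smallest grand-mean deviance is selected; exact ties break
towards parsimony (fewer total leaves, then fewer trees — ties are not
discussed in the source protocol, so this is the package's rule).  The
**representative repeat** — the one whose cell mean is closest to the
grand mean — identifies a typical rather than extreme split for
reporting, and the final reported model is refit on the *full* data at the
selected complexity (matching the convention of quoting one set of odds
ratios for the whole cohort; refitting on the representative training
split is the plausible alternative and is available by calling
`anneal_fit()` on that split directly).

## The synthetic cohort

The original cohort links a population cancer registry to insurance
claims and is restricted; nothing in it can be redistributed.  The
generator (`default_cohort_spec()`, `generate_covariates()`,
`simulate_study()`) therefore emulates its *structure* so that the whole
pipeline is exercisable and testable:

* **Scale.** Defaults are the study-scale conditions — 11,918 patients
  nested in 2,088 surgeons.  The committed analyses run at 3,000 patients
  / 550 surgeons to keep runtimes in seconds-to-minutes; tests use sizes
  from 200 to 5,000 stated in each test.
* **Margins.** Covariate marginal frequencies are read off the embedded
  printed tables (`fixtures()`): patient variables (age band, race,
  gender, marital status, socioeconomic stratum, comorbidity count, tumor
  size band, histology) and surgeon variables (age band, gender,
  graduation-year band, practice structure, academic affiliation,
  rural/urban, cancer-center affiliation).  Continuous quantities are
  drawn directly as bands at the clinical cutpoints, since only the
  binarised versions ever enter the model.
* **Nesting.** Patients are assigned to surgeons with probability
  proportional to geometric surgeon weights (expected caseload =
  patients/surgeons), reproducing the many-low-volume-provider skew
  (median caseload near 4 at full scale, far below the mean).  Surgeon
  variables are drawn once per surgeon — patient-weighted margins applied
  at the surgeon level, a deliberate simplification.  Two volume summaries
  derive from realised caseloads: quartile bands, and the high-volume flag
  at the caseload 83rd percentile (the empirical "≥3 annual
  nephrectomies" rule).
* **Outcomes.** Outcomes are planted through the generative inverse of
  the model above: per-row probabilities
  \(\operatorname{logit}^{-1}(\beta_0 + \sum_j \beta_j L_j)\) with Boolean
  rules mirroring the published findings — tumor ≤ 4 cm (odds ratio 5.9)
  and an unfavourable practice-environment clause (odds ratio 0.30) for
  partial nephrectomy; major academic affiliation (2.12), a
  large-tumor/early-graduation/solo-practice clause (0.38), and a
  low-volume/rural/early-graduation clause (0.29) for laparoscopy among
  radical nephrectomies.  Intercepts are calibrated by root-finding so the
  expected rates hit the published base rates (15.2% partial nephrectomy;
  20.6% laparoscopy among radical nephrectomy).  Laparoscopy among
  partial-nephrectomy patients is assigned at its marginal rate purely to
  label the four procedures for descriptive tables.
* **RNG discipline.** Every variable draws from its own substream keyed
  by (master seed, variable name), so adding a variable to a spec leaves
  previously generated columns byte-identical.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: covariates are drawn independently (no
joint surgeon–patient correlation structure is published, so none is
invented), there are no temporal trends across diagnosis years, no
claims-coding noise, and outcome probabilities follow the logistic-rule
model exactly.  Tests on this cohort validate the *machinery* —
recoding, search, selection, reporting — not the epidemiology.

## Binary recoding

`build_default_schema()` encodes the cohort at the standard clinical
cutpoints: tumor size at 4 cm; patient age in five-year bands (65–69 …
≥85); comorbidity 0/1/≥2; graduation year <1960, 1961–70, 1971–80,
1981–90, ≥1991; surgeon age <40, 40–49, 50–59, ≥60; practice structure,
affiliation, race as indicator sets; married/rural/NCI/high-volume as
single indicators.  Bands are emitted as mutually exclusive one-hot
indicators rather than cumulative thresholds — that is how the category
lists read, and the Boolean search can synthesise any cumulative effect
with an OR — but the choice is worth a sensitivity look on real data.
Rows with missing values in modeled variables are dropped with a logged
count (complete-case; conservative for claims data).  A provenance map
ties every encoded column back to its raw variable and level, and the
encoding is invertible row by row (`decode_design()`).

## Reporting

`crosstab()`/`chisq_screen()` reproduce the descriptive layout: counts
with one-decimal row percentages and Pearson chi-square screens without
continuity correction (the tables are large; the screen is descriptive).
A low-expected-count flag attaches below expected count 1.  `auc()` is
the Mann–Whitney concordance probability computed from midranks — exact
under ties and invariant to monotone transforms, unlike a thresholded
trapezoid.  `render_model_report()` prints each tree as an and/or/not
expression with `exp(β)` and Wald 95% intervals on the log-odds scale —
the intervals are *naive refit* intervals that do not account for the
preceding search, which matches the published reporting convention and
should be read accordingly.

## Validation strategy

The test suite rests on oracles that are independent of the code paths
they check:

* the embedded printed tables, whose every count, total, and one-decimal
  percentage is recomputed (23 of 204 printed percentages are off by
  exactly one final-decimal unit against their own counts; they are
  frozen as known print errata and asserted to differ by exactly 0.1);
* exhaustive enumeration of all trees with ≤3 leaves on small designs
  (`exhaustive_search()`), against which the annealed search must attain
  the same global deviance minimum in ≥95% of seeds;
* closed-form 2×2 arithmetic (the single-split deviance and the
  cross-product odds ratio, e.g. 6.57 for the tumor-size table), which
  the IRLS must reproduce to 10⁻⁶, cross-checked against `glm()`;
* planted generative truth: the rule `X1 AND (X2 OR X3)` (β = 1.5,
  n = 5,000, ten noise predictors) must be recovered — up to Boolean
  equivalence after sign orientation — in ≥80% of seeds, and a planted
  two-rule model (opposite-signed effects, so no single tree can absorb
  both) must lead repeated CV to select two trees in ≥70% of replications;
* a null calibration: on outcomes independent of all predictors, the
  annealed model must not beat the intercept-only model on held-out
  deviance beyond chance (paired one-sided test across seeds).

## Known limitations

Standard errors ignore surgeon-level clustering (as in the published
intervals).  The annealer offers no MCMC model averaging or greedy
alternative.  The published AUCs (0.77 and 0.71 for the two endpoints)
and fitted odds ratios were computed on the restricted cohort and are
context, not reproducible targets; the synthetic pipeline recovers its
own planted effects instead.  Percentages in the embedded tables carry
the print errata noted above.
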