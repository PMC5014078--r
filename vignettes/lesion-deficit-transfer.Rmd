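---
title: "Lesion-deficit prognostic models and cross-group transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-deficit prognostic models and cross-group transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionprog)
```

## The analysis problem

After a left-hemisphere stroke, language outcomes depend on where and how
much tissue was destroyed, and on how much time has passed.  Prognostic
models learn this lesion-deficit mapping in one patient group — typically
a large reference group — and are then asked to predict outcomes for
patients outside that group.  `lesionprog` implements a complete pipeline
for the question *does a model learned in group a transfer to group b,
and if it fails, why?* Its concrete motivating case is a large group of
native speakers (group a) and a smaller group of non-native speakers
(group b) assessed on the same standardized language battery, but nothing
in the code is specific to that pairing.

The pipeline has four stages:

1. **Lesion encoding.** Binary lesion masks in a standard space are
   reduced to *lesion load* — the percentage of each parcellation
   region's voxels destroyed (0–100) — plus total lesion volume, time
   post-stroke, sex and age.  With a 199-region parcellation this yields
   203 predictors per patient.  Regions may overlap (a union of several
   anatomical atlases); no disjointness is assumed anywhere.
2. **Model selection.** For each task score, a linear model is selected
   by iterated forward-selection/backwards-elimination over the
   predictors, scored by leave-one-out cross-validated (LOOCV) mean
   absolute error, starting from time post-stroke alone.
3. **Transfer evaluation.** Group a is predicted by LOOCV; group b by a
   single model trained on all of group a.  Per-task prediction-error
   shifts (error = predicted − actual, so positive means
   *overestimation*) are tested with independent-samples t-tests under a
   permutation-based family-wise threshold, and the result is
   stress-tested with an ensemble of random feature sets.
4. **Region-wise associations.** Per (region, task, group), the Pearson
   correlation between lesion load and score is converted into a default
   Bayes factor; the screen asks whether associations that are strong in
   group b are also strong in group a (*neural convergence*) or not
   (*neural divergence*), and compares the groups' regression slopes in
   the shared cases.

A synthetic-cohort generator stands in for clinical data, so every stage
is testable end to end.

## The synthetic-cohort generator

`generate_cohort()` draws, in order: a toy atlas of compact, possibly
overlapping regions grown on a voxel grid (default 24×28×24 voxels of
8 mm³); territory-structured focal lesions (each lesion a single
connected component of at least 1 cm³, grown from a seed scattered
around one of a small number of territory centres — a crude stand-in
for vascular territories); demographics (sex, age at stroke, time
post-stroke from a lognormal with median ≈ 37 months, truncated at 3
months); and task scores that are *linear* in the predictors:

\[
y_{it} \;=\; \beta_{0t} + \sum_r w_{tr}\,\mathrm{load}_{ir}
 + w^{\mathrm{time}}_t\,\mathrm{tps}_i + \varepsilon_{it},
 \qquad \varepsilon_{it}\sim N(0,\sigma^2).
\]

Lesion-load weights \(w_{tr}\) are negative — damage lowers scores — with
magnitudes drawn once per task from a configurable range (default
0.04–0.12 T-score units per percent load, 5 active regions per task),
and the time coefficient is small and positive (slow recovery, default
0.02 per month).  Group b differs from group a through exactly two
knobs, kept separate because they formalize two different explanations
of a transfer failure:

* `lambda_sensitivity` (λ) multiplies group b's lesion-load weights —
  *enhanced sensitivity to damage in a shared network*;
* `intercept_shift` (δ) adds a constant to group b's expected scores —
  a lesion-independent main effect such as premorbid proficiency
  differences.

Raw scores are standardized to T-scores against a simulated reference
sample of 60 lesioned patients (mean 50, SD 10 by construction), with an
impairment cutoff at the 5th percentile of 27 simulated controls; the
raw-score scale itself is a free choice, since only the standardized
scale is analysed.  Missingness is missing-completely-at-random per task
(default 3%, matching the small per-task attrition typical of aphasia
batteries); the analysis makes no assumption about why entries are
missing and simply uses each task's complete cases.  Group sizes default
to 174 and 33.  For 7 of the tasks, group b additionally receives
native-language scores a few T-units below their main scores, and
language-history fields (number of languages, age of acquisition, years
of use, self-rated proficiency and usage) are simulated with realistic
per-question response rates; by default they are independent of outcomes
(a null screen), with an optional injected association for power
checks.

What the generator does **not** emulate: real psychometrics (floor and
ceiling effects, discreteness), real vascular anatomy, spatial
normalization error, and — importantly — the empirical covariance of
task scores, which in real batteries is much higher than the overlap
induced here by shared lesion geometry.  Passing tests therefore
demonstrate that the *pipeline* behaves correctly under its assumed
generative model, not that real cohorts satisfy those assumptions.

## Numerical and procedural choices

**Least squares and LOOCV.**  Fits use QR decomposition; rank-deficient
designs fall back to the minimum-norm (pseudoinverse) solution, so
duplicated predictors share weight equally and every fold is defined.
LOOCV predictions use the exact closed form \(\hat e_i = e_i/(1-h_{ii})\)
when the design is full rank (identical to refitting n times), and
per-fold refits otherwise.

**Feature search.**  A step is accepted only if it improves the LOOCV
criterion by more than 1e-9, which makes the accepted-step criterion
strictly decreasing, bounded below by zero — hence the search always
terminates.  Candidate ties break to the lowest column index, making the
search fully deterministic.  The seed feature (time post-stroke) is not
protected from elimination: its retention in selected models is a
result, not a constraint.  Zero-variance candidates within a task's
complete cases are skipped.  The criterion is mean absolute error by
default (the quantity the per-task performance tables report); RMSE is
available by option.

**Shift tests.**  Pooled-variance t-tests are used after a Levene
pre-check (classic form: ANOVA on absolute deviations from group means);
if the pre-check rejects at 0.05, Welch's form replaces the pooled test.
All tests are two-sided.

**Permutation family-wise threshold.**  One global permutation of group
labels is drawn per iteration and applied within each task's complete
cases, so the between-task correlation of the statistics is preserved;
the corrected per-test alpha is the 5% quantile of the per-permutation
*minimum* p-value (min-p/max-statistic control), capped at the nominal
alpha.  With a single task this reduces to no correction; with k
independent tasks it approaches the Bonferroni level from above — for
correlated tasks it sits in between, which is why a corrected threshold
well above alpha/k is expected for a correlated battery.

**Random-model ensemble.**  Feature-set sizes are uniform on 2–40 by
default (bracketing, with margin, the 18–36-predictor range that
selected models typically span), members uniform without replacement
over all predictors.  Each random set is pushed through the identical
transfer-and-test machinery at the already-corrected threshold.

**Correlation Bayes factor.**  The default test of a correlation given
only (r, n) compares a regression model with a JZS-class g-prior on the
standardized slope against an intercept-plus-noise null:

\[
\mathrm{BF}_{10} = \frac{\sqrt{n/2}}{\Gamma(1/2)} \int_0^\infty
 (1+g)^{(n-2)/2}\bigl[1+(1-r^2)g\bigr]^{-(n-1)/2} g^{-3/2}
 e^{-n/(2g)}\,dg .
\]

The integral is evaluated by adaptive quadrature in \(t=\log g\) (the
peak then never collides with a domain boundary), split at the
integrand's peak and restricted to its effective support, on the log
scale; failures raise an error rather than returning a default.  The
result is symmetric in the sign of r, strictly increasing in |r| at
fixed n, and matches a 10⁶-node dense-grid oracle to better than 1e-6
relative error.  Evidence categories follow the conventional 10, 3,
1/3, 1/10 thresholds (strong/substantial for the correlation,
substantial/strong for the null, inconclusive between).  No
multiplicity correction is applied inside the screen — the categories
are descriptive evidence grades, not corrected decisions.

**Connected components.**  Lesion contiguity uses 26-connectivity by
default (any shared corner), configurable to 6 or 18; the 1 cm³
focality rule is computed from voxel volume, not voxel count, so
non-1 mm³ grids behave correctly.  Components are labelled via a
vectorised voxel-adjacency graph (igraph).

**Sex coding** is 0 = female, 1 = male; coefficient signs depend on it.

## Validation studies and the problem sizes used

The test suite runs four simulation studies, with sizes chosen to make
each study's Monte-Carlo error small relative to the property being
asserted:

* **Null calibration** of the full pipeline (selection → transfer →
  permutation threshold) uses 500 replicates at n = (120, 30), 12
  regions, 6 tasks, 200 permutations, asserting a family-wise flag rate
  in [0.02, 0.09].  The group sizes keep the 4:1 ratio of the motivating
  design but are large enough that a small-sample artifact stays
  negligible: at much smaller n, the feature search overfits the
  reference group, group b's error variance exceeds group a's
  LOOCV-error variance, and the pooled t over an unbalanced split
  becomes anticonservative in a way the label-permutation null (which
  assumes exchangeability) cannot absorb.
* **Power**: with λ = 1.5 at the same scale, a corrected positive shift
  is detected, and the transfer group overestimated, in ≥ 95% of 100
  replicates.
* **Sensitivity-multiplier recovery**: the median ratio of group-b to
  group-a univariate slopes over generatively active cells recovers λ
  within ±10%.  This study draws region loads independently
  (`cohort_from_loads()`) rather than from lesion geometry: with
  territory-structured lesions, loads are strongly collinear across
  regions, each univariate slope mixes neighbouring regions'
  contributions, and per-cell ratios carry ~10% spread even at very
  large n — a limitation of region-wise univariate slopes worth knowing
  about when interpreting slope comparisons on real data.
* **Convergence screen**: a convergent generator (shared weights,
  λ = 1.5, dense severity-structured loads so every region is solidly
  covered in both groups) yields a strong-in-b set that is ≥ 90% shared
  with group a and a positive paired slope-comparison t; a divergent
  generator (one region weighted only in group b) puts exactly that
  region on the divergent list.  With mask-based geometry and a small
  transfer group, regions lesioned in only a handful of group-b
  patients can produce spurious strong-in-b correlations whose group-a
  Bayes factor is small — so on real small groups the divergent list
  should be read alongside each case's group-a Bayes factor, which the
  screen reports for this reason.

## Known limitations

* Linear models only, by design; no regularization or nonlinear
  expansion.
* The permutation scheme assumes group labels are exchangeable under
  the null given the fixed predictions; strong group differences in
  error *variance* (as opposed to mean) can still register.
* Region-wise univariate slopes are confounded across collinear
  regions (see above); the multivariate model coefficients are not
  reused in the screen, deliberately, to keep the association analysis
  region-local.
* The screen's complete-case n varies per (region, task, group) and is
  reported in every row; Bayes factors for barely-lesioned regions rest
  on few informative observations even when n is nominally large.

## A small worked run

```{r demo, eval = FALSE}
cfg <- simulation_config(n_group_a = 60, n_group_b = 15,
                         n_regions = 20, n_tasks = 2,
                         lambda_sensitivity = 1.5, seed = 7)
cohort <- generate_cohort(cfg)
run <- run_pipeline(cohort, n_perm = 200, n_random_models = 50, seed = 3)
run$shift          # per-task t, p, corrected threshold, group error means
run$flagged_tasks  # tasks with a corrected positive shift
run$screen         # Bayes-factor convergence screen over flagged tasks
```
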