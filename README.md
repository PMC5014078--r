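# lesionprog

Lesion-deficit prognostic modelling and cross-group transfer analysis
for post-stroke language outcomes.

## The problem

Prognostic models for post-stroke aphasia learn how language scores
depend on *where* the lesion is (per-region lesion load), *how big* it
is, and *how long ago* the stroke happened — usually in a large,
relatively homogeneous reference group. Clinically, those models are
then applied to patients who were not represented in the training
group. `lesionprog` is a pipeline for asking whether such a model
*transfers*: do its predictions for a second group show a systematic
shift, is that shift specific to the selected model or generic across
the model space, and does it come with differences in the underlying
region-wise lesion-deficit associations (distinct regions — *neural
divergence* — versus the same regions loaded more heavily — *neural
convergence*)?

It is aimed at researchers running lesion-symptom mapping or prognosis
studies who want the full chain — encoding, selection, transfer testing,
Bayes-factor screening — as tested, reusable, scriptable components,
plus a synthetic-cohort generator for method validation.

## The method

For each task score *y* the pipeline selects a linear model
*y* = β₀ + Σᵣ βᵣ·loadᵣ + β_t·tps + … over up to 203 predictors
(199 region loads + lesion volume + time post-stroke + sex + age) by
iterated forward-selection / backwards-elimination, scored by
leave-one-out cross-validated mean absolute error and seeded with time
post-stroke. Group a is predicted by LOOCV, group b in a single pass by
a model trained on all of group a; errors follow the convention
error = predicted − actual (positive = overestimation). Per-task shifts
are tested with independent-samples t-tests (Levene-gated pooled
variance) under a min-p/max-statistic permutation family-wise threshold,
and re-run across an ensemble of random feature sets. Region-wise
associations use the default Bayes factor for a correlation given
(r, n) — a JZS-class g-prior test against an intercept-plus-noise
null, evaluated by adaptive quadrature — with Jeffreys-style evidence
categories at 10, 3, 1/3, 1/10, a shared-versus-divergent screen, and a
paired comparison of univariate slopes in shared cases.

## A worked example

```r
library(lesionprog)

cfg <- simulation_config(n_group_a = 60, n_group_b = 15,
                         n_regions = 20, n_tasks = 2,
                         lambda_sensitivity = 1.5, seed = 7)
cohort <- generate_cohort(cfg)
run <- run_pipeline(cohort, n_perm = 200, n_random_models = 50, seed = 3)
run$shift
#>      task        t         p mean_error_a mean_error_b ... threshold
#> 1 task_01 1.322331 0.1902431   0.03662444    2.5681494 ... 0.02719829
#> 2 task_02 -0.601816 0.5491872   0.12708308   -0.8019621 ... 0.02719829
```

Here group b was simulated 1.5× as sensitive to lesion damage
(`lambda_sensitivity = 1.5`): its prediction errors on `task_01` are
positively shifted (+2.57 T-score units on average — the group-a model
overestimates these patients), but at this small demo size (15 transfer
patients, 2 tasks) the shift does not clear the permutation-corrected
threshold of 0.027. At the package's default study scale (174 + 33
patients) the same analysis flags most tasks, as the acceptance script
shows.

A full run also returns `run$ensemble` (fraction of random models
reproducing the flagged shifts, plus opposite-direction count),
`run$screen` (region×task Bayes-factor convergence screen),
`run$slopes` (paired slope comparison over shared strong cases) and
`run$history` (language-history screen against prediction errors).

Cohorts round-trip to flat files (NIfTI-1 masks, TSV tables, JSON
config) via `write_cohort()` / `read_cohort()`; a thin CLI wrapper over
the same functions is in `inst/cli/lesionprog.R`.

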