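# stagebd

Clinical staging of bipolar disorder from multidomain severity profilers.

Bipolar disorder behaves as a life-course illness: presentations shift from
mild early forms to severe late ones, and clinicians increasingly want to
place a patient on that trajectory rather than only label an episode.
`stagebd` implements an empirically derived five-stage staging model for
researchers and clinical data analysts. Twelve patient-level *profilers*
from five life domains — clinical course (hospitalizations, suicide
attempts, comorbid personality disorder), physical health (BMI, metabolic
syndrome, comorbid physical illnesses), cognition (SCIP category),
functioning (permanent disability, FAST total and leisure), and quality of
life (SF-36 physical functioning and mental health) — are normalised to
[0, 1] and combined into a global severity score

```
Severity = 10/12 * (PDxBD + MetS + ComPD + SCIP + IllnessN + SFPF + SFMH
                    + FAST_T + FAST_leisure + BMI + HospN + SuicAttN)
```

which ranges from 0 to 10. Percentile-derived cutoffs (1.70, 2.50, 4.50,
6.10) partition it into stages 1–5, with a score of exactly 6.10 in stage 4
and ≥ 6.11 in stage 5.

The package covers the whole validation pipeline around that score:

* **Transforms** — a configurable registry mapping each raw profiler to the
  unit interval (`default_transform_registry()`, YAML round-trip).
* **Scoring and staging** — `score_cohort()`, `assign_stage()`,
  `calibrate_cutoffs()`.
* **Construct validity** — `build_validity_report()`: stage-wise ANOVA and
  chi-square tests, Tukey post-hoc contrasts, GAF and drug-pattern external
  validators, monotone-worsening flags.
* **Longitudinal validity** — `transition_matrix()`,
  `shift_expectations_check()`, `euthymic_subgroup_analysis()` with paired
  t-tests on life-domain composites.
* **Synthetic cohorts** — `cohort_config()` / `simulate_cohort()`: seeded,
  stage-structured longitudinal cohorts with the published stage mix,
  per-stage profiler distributions, transition kernel, 32.2% sustained
  euthymia and 57.6% retention, so the pipeline is fully testable without
  patient-level data.

Everything is tibble-first and pipe-friendly; results have `tidy()` /
`glance()` methods and `plot_*()` ggplot helpers.

## Worked example

```r
library(stagebd)

sim <- simulate_cohort(cohort_config(n_baseline = 129, seed = 2024))
scored <- score_cohort(sim$followup)
summarise_cohort(scored)$severity
#> # A tibble: 1 x 5
#>       n  mean    sd   min   max
#>   <int> <dbl> <dbl> <dbl> <dbl>
#> 1    66  3.60  1.57  1.04  7.51

glance(transition_matrix(sim$pairs))
#> # A tibble: 1 x 6
#>       n  same one_stage two_plus progressed regressed
#>   <int> <dbl>     <dbl>    <dbl>      <dbl>     <dbl>
#> 1    66 0.515     0.439   0.0455      0.258     0.227
```

The simulated 129-patient cohort loses ~42% to attrition (the configured
57.6% retention), scores a follow-up mean severity of 3.60 (the published
cohort printed 3.6), and over three years 51.5% of completers stay at their
stage, 43.9% move one stage, and 4.6% move two or more — the "mostly local
movement" signature a valid staging model should show. Per-patient output
is one row per patient with `severity` (0–10) and `stage` (1–5) columns.

A full account of the model, the transform defaults, the monotone-worsening
rule, and what the generator does and does not emulate is in the methods
vignette: `vignettes/staging-model-methods.Rmd`.

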