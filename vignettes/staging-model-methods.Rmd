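---
title: "Methods: the five-stage severity model and its validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the five-stage severity model and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagebd)
library(dplyr)
```

## The model

Bipolar disorder is increasingly understood as a life-course illness that
progresses from mild early presentations to severe late ones. `stagebd`
implements an empirically derived clinical staging model built on twelve
patient-level *profilers* spanning five life domains:

| Domain | Profilers |
|---|---|
| Clinical course | number of hospitalizations, number of suicide attempts, comorbid personality disorder |
| Physical health | BMI, metabolic syndrome, number of comorbid physical illnesses |
| Cognition | SCIP impairment category |
| Functioning | permanent disability due to the disorder, FAST total (0–72), FAST leisure (0–6) |
| Quality of life | SF-36 physical functioning and mental health z-scores |

Each profiler is first mapped to the unit interval so that 0 means no
burden and 1 means maximal burden. The global severity score is then

$$\mathrm{Severity} = \frac{10}{12}\sum_{j=1}^{12} x_j, \qquad x_j \in [0,1],$$

so every profiler carries equal weight and the score ranges from 0 to 10.
Four percentile-derived cutoffs (1.70, 2.50, 4.50, 6.10 by default)
partition the axis into five stages: stage 1 is $[0, 1.70]$, each interior
stage is a half-open interval $(c_{s-1}, c_s]$, and stage 5 is
$(6.10, 10]$. The upper-inclusive convention is forced by the published
boundary description, under which a score of exactly 6.10 belongs to stage
4 and 6.11 or more to stage 5. `calibrate_cutoffs()` re-derives boundaries
from a severity sample as empirical percentiles; we use the
linear-interpolation percentile definition (`quantile` type 7), the most
common convention, because none is named in the source material.

## Transform choices

The source tables publish transformed cohort *means* but not the transform
functions, so the transforms are a documented, overridable registry
(`default_transform_registry()`, shipped as
`inst/extdata/default_transforms.yaml`):

* **Counts** are capped and scaled: hospitalizations and suicide attempts
  at 6, physical illnesses at 4. A count at or beyond the cap contributes
  exactly 1. These caps approximately reproduce the published transformed
  means (e.g. a mean of 1.2 hospitalizations maps near the published 0.19).
* **Binaries** pass through, so transformed means equal prevalences exactly
  (23/129 comorbid personality disorder gives the published 0.18).
* **FAST** scores rescale linearly by instrument range (26.8/72 = 0.372,
  printing as the published 0.37).
* **SCIP** categories map to equally spaced quartile values
  (none 0, mild 1/3, moderate 2/3, severe 1).
* **BMI** uses the WHO step map: below 25 contributes 0, 25–29.9 one half,
  30 and over 1. A step map cannot reproduce a cohort mean from a mean BMI
  (transform of the mean is not the mean of transforms), which is why the
  published pair (direct 24.5, transformed 0.15) is only loosely matched.
* **SF-36 z-scores** ramp linearly and *decreasingly* over $[-3, +3]$:
  higher z means better health, so $x = (3 - z)/6$, clipped.

Two published inconsistencies cannot be resolved from the printed numbers
alone and are simply documented: a FAST leisure baseline mean of 3.0 with
SD 7.1 on a 0–6 subscale, and a SCIP transformed mean of 0.47 where the
printed category proportions imply roughly 0.41 under any monotone
quartile map.

Missing raw values propagate as `NA` severity and stage; they are never
silently zero-filled, which would bias severity downward.

## The validity battery

`build_validity_report()` reproduces the construct-validity analyses:
one-way ANOVA across stages for continuous profilers and GAF, Pearson
chi-square (no continuity correction, asymptotic p-values, with a warning
when an expected count falls below 5) for categorical profilers and drug
patterns, and Tukey HSD available for post-hoc pairwise contrasts. No
multiple-testing correction is applied, matching the original analysis;
the report header says so.

Because several published stage denominators disagree with the stage
headers, contingency tests take explicit denominators reconstructed from
the printed percentages; three of the published drug statistics are only
reproducible that way.

Each profiler also gets a **monotone-worsening flag**. Stage-wise means on
the transformed scale should rise from stage 1 to stage 5. We flag a
profiler as worsening when (a) the stage-5 mean exceeds the stage-1 mean
and (b) no consecutive dip exceeds one quarter of the span of the five
stage means. The relative-dip rule absorbs sampling noise and the small
configured reversal in the SCIP defaults (0.613 at stage 4 vs 0.593 at
stage 5 on the transformed scale) while still rejecting profiles that
trend the wrong way: the SF-36 mental-health profiler reverses direction
and dips by its entire span, so it is never flagged — matching the one
profiler that failed to worsen significantly in the original cohort.

## Longitudinal analysis

`transition_matrix()` cross-tabulates baseline against follow-up stages
and reports exact aggregate fractions (same stage, one stage, two or more
stages, progressed, regressed). `shift_expectations_check()` encodes the
expectation that over a 3-year window fewer than 10% of patients move two
or more stages. `euthymic_subgroup_analysis()` restricts to patients
euthymic throughout follow-up and runs paired t-tests on life-domain
composites — defined here as the mean of each domain's transformed
profilers, since the source does not define its "dimensions"
operationally — separately for patients who remained at the same stage and
those who regressed.

## The synthetic cohort generator

No public patient-level data exist, so `cohort_config()` +
`simulate_cohort()` generate cohorts with the published stage structure.
The defaults *are* the study conditions: baseline stage mix
10.9/15.5/47.3/18.6/7.8% (the follow-up classification proportions,
documented stand-in for unprinted baseline proportions), per-stage
profiler means and SDs from the published stage table, 32.2% sustained
euthymia, 57.6% retention (missing completely at random, since followed
and lost patients had indistinguishable severity), and a transition kernel
assembled from the published row-wise shift percentages. Where the
published stage-3 row says "18.2% regressed or progressed one stage", we
read 18.2% in each direction and renormalise the row. Euthymic patients
evolve under a separate kernel shaped from the published euthymic
aggregates (55.3% same, 23.7% regress one, 15.8% progress one, 5.3%
regress two, with impossible moves at the stage boundaries folded into
"same"); strictly, the main kernel summarises the whole cohort, so using
it for non-euthymic patients is an approximation we document rather than
hide.

Distribution families are not published, so the generator uses the
simplest families consistent with the printed moments and supports:
negative binomial for overdispersed counts (falling back to Poisson when
the printed SD implies no overdispersion, e.g. stage-1 hospitalizations
0.7 with SD 0.3), Bernoulli for binaries, truncated normals for bounded
scales (FAST, BMI, GAF; integer-rounded where the instrument is integral),
and normals for z-scores. Only the per-stage "no cognitive impairment"
fraction is published for SCIP, so the remaining mass is split equally
over mild/moderate/severe.

**Label consistency.** Sampling profilers from a stage's marginal
distributions does not guarantee the resulting severity lands in that
stage's interval. With `rejection_sampling = TRUE` (default) a patient's
profile is redrawn (up to `max_tries = 1000`) until it does, making the
generated label exact by construction; with it off, label confusion
concentrates on adjacent stages. All randomness flows through the single
config seed, and identical configs produce byte-identical cohorts.

What the generator does *not* emulate: within-patient correlation between
profilers beyond what the shared stage induces, within-patient
autocorrelation of profiler values across timepoints (follow-up profiles
are fresh draws from the target stage), item-level psychometrics, and
severity-dependent dropout (a knob exists for sensitivity analyses in the
config but defaults to MCAR). Passing tests on these cohorts therefore
show that the pipeline recovers the structure it was configured with —
not that the staging model is valid in new clinical data.

## Problem sizes and numerical choices

The test suite exercises cohorts of 20–4,000 patients and one
10,000-patient kernel-recovery run (empirical row-conditional transition
frequencies within 3 binomial standard errors of the configured kernel),
sizes chosen so Monte-Carlo error is small relative to the tolerances
being checked. Severity is kept at full precision throughout; rounding to
the published presentation precision (1–2 decimals) happens only in
reports. Degenerate inputs are handled explicitly: constant severity
samples are a calibration error (tied percentile cutoffs cannot partition
the axis), all-constant ANOVA groups return F = 0 by convention,
zero-variance paired differences return the limiting t of 0 (or signed
infinity for a constant nonzero shift), and single-stage cohorts skip
between-stage tests with a note rather than erroring.

## Limitations

The transforms and distribution families are reconstructions constrained
by published summary statistics, not the original study's code; the
original five clusters came from a k-means analysis on a different
(baseline) sample that this package deliberately does not re-derive. The
published stage tables contain internal inconsistencies (stage counts
vs. percentages) that the package handles by taking denominators as
explicit inputs. Cutoff calibration is exposed as an explicit operation
because the sample on which the original percentile cutoffs were computed
is not fully specified.
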