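Package: stagebd
Title: Clinical Staging of Bipolar Disorder from Multidomain Severity Profilers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an empirically derived five-stage clinical staging
    model for bipolar disorder. Twelve clinical profilers spanning five life
    domains (clinical course, physical health, cognition, real-world
    functioning, and health-related quality of life) are normalised to the
    unit interval, combined into a global severity score on a 0-10 scale,
    and mapped to stages through percentile-based cutoffs. The package also
    provides the accompanying construct-validity battery (stage-wise ANOVA,
    chi-square tests, Tukey post-hoc comparisons, paired t-tests), a
    longitudinal stage-transition analysis, and a seeded synthetic-cohort
    generator that emulates stage-structured clinical data so every step of
    the pipeline can be exercised without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
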