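# Per-stage distribution parameters for the synthetic generator. Counts are
# negative-binomial (Poisson when the stated SD implies no overdispersion),
# binaries Bernoulli, bounded scales truncated normal, z-scores normal.
default_stage_params <- function() {
  list(
    hosp_n       = list(kind = "count", mean = c(0.7, 0.3, 0.8, 2.0, 5.8),
                        sd = c(0.3, 0.6, 1.1, 1.9, 4.2)),
    suic_att_n   = list(kind = "count", mean = c(0.1, 0.3, 0.5, 1.8, 5.6),
                        sd = c(0.3, 0.6, 0.9, 1.6, 4.8)),
    com_pd       = list(kind = "binary", p = c(0, 0, 0.443, 0.32, 0.667)),
    bmi          = list(kind = "truncnorm", mean = c(21.2, 21.6, 25.3, 26.0, 28.5),
                        sd = c(4.2, 4.0, 4.5, 4.5, 5.6), lo = 13, hi = 60),
    mets         = list(kind = "binary", p = c(0, 0.05, 0.443, 0.68, 0.667)),
    illness_n    = list(kind = "count", mean = c(0.3, 0.8, 1.9, 2.5, 2.4),
                        sd = c(0.6, 1.0, 1.7, 1.6, 1.6)),
    # only the no-impairment fraction is pinned per stage; the remaining
    # probability mass is split equally over mild/moderate/severe
    scip_cat     = list(kind = "categorical", levels = scip_levels,
                        probs = t(vapply(c(0.929, 0.550, 0.400, 0.080, 0.111),
                                         function(p0) c(p0, rep((1 - p0) / 3, 3)),
                                         numeric(4)))),
    pd_x_bd      = list(kind = "binary", p = c(0, 0.20, 0.492, 0.75, 1)),
    fast_total   = list(kind = "truncnorm_int", mean = c(8.3, 15.6, 26.5, 38.0, 55.9),
                        sd = c(6.7, 10.2, 11.4, 11.7, 9.2), lo = 0, hi = 72),
    fast_leisure = list(kind = "truncnorm_int", mean = c(0.4, 1.2, 2.2, 3.3, 5.5),
                        sd = c(0.6, 1.8, 1.9, 2.0, 0.9), lo = 0, hi = 6),
    sf_pf        = list(kind = "normal", mean = c(0.3, 0.2, -0.5, -0.8, -1.7),
                        sd = c(0.4, 0.7, 1.0, 1.2, 1.1)),
    sf_mh        = list(kind = "normal", mean = c(-0.7, -0.3, -0.6, -0.6, -0.5),
                        sd = c(0.4, 0.6, 0.6, 0.7, 0.5))
  )
}

# Baseline-to-follow-up stage kernel. Stage 3's equal one-step splits are a
# documented reading of an ambiguous summary; each row is renormalised.
default_transition_kernel <- function() {
  k <- rbind(
    c(0.333, 0.500, 0.167, 0.000, 0.000),
    c(0.276, 0.311, 0.379, 0.034, 0.000),
    c(0.000, 0.182, 0.633, 0.182, 0.000),
    c(0.000, 0.000, 0.320, 0.417, 0.263),
    c(0.000, 0.000, 0.111, 0.556, 0.333)
  )
  k / rowSums(k)
}

# Kernel for patients euthymic throughout follow-up, shaped from the
# subgroup aggregates (55.3% same, 23.7% regress one, 15.8% progress one,
# 5.3% regress two); moves off the stage axis fold into "same".
default_euthymic_kernel <- function() {
  k <- matrix(0, 5, 5)
  for (s in 1:5) {
    add <- function(target, p) {
      t2 <- min(max(target, 1), 5)
      k[s, t2] <<- k[s, t2] + p
    }
    add(s, 0.553); add(s - 1, 0.237); add(s + 1, 0.158); add(s - 2, 0.053)
  }
  k / rowSums(k)
}

default_gaf_params <- function() {
  list(mean = c(81.1, 79.5, 67.6, 62.3, 47.2),
       sd = c(11.9, 9.2, 11.4, 10.8, 12.0), lo = 1, hi = 100)
}

# Drug-pattern distributions per stage (columns = stages). The prescribed
# drug-count categories come from the printed stage percentages, renormalised.
default_drug_params <- function() {
  n_drugs <- cbind(
    c(30.8, 38.5, 7.7, 15.4, 7.7),
    c(26.3, 42.1, 21.1, 5.3, 5.3),
    c(3.7, 25.9, 27.8, 22.2, 13.0),
    c(4.5, 13.6, 31.8, 22.7, 18.2),
    c(0, 0, 0, 55.6, 44.4)
  )
  n_drugs <- sweep(n_drugs, 2, colSums(n_drugs), "/")
  rownames(n_drugs) <- c("one", "two", "three", "four", "five_plus")
  list(
    n_drugs_cat = n_drugs,
    antipsychotics = c(0.500, 0.400, 0.607, 0.667, 0.808),
    antidepressants = c(0.214, 0.300, 0.517, 0.458, 0.900),
    benzodiazepines = c(0.214, 0.316, 0.508, 0.667, 0.800)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the generator: cohort size, baseline stage
#' distribution, per-stage profiler distributions, the stage-transition
#' kernel (plus a separate kernel for patients euthymic throughout
#' follow-up), the sustained-euthymia probability, the 3-year retention
#' probability, and external-validator (GAF, drug-pattern) distributions.
#' The defaults encode the published stage-structured cohort: stage mix
#' 10.9/15.5/47.3/18.6/7.8%, 32.2% sustained euthymia, 57.6% retention.
#'
#' @param n_baseline Number of patients at baseline.
#' @param stage_dist Five baseline stage probabilities (sum to 1).
#' @param stage_params Per-stage profiler distribution parameters; override
#'   entries of the default list to change families or moments.
#' @param kernel 5x5 row-stochastic baseline-to-follow-up stage kernel.
#' @param euthymic_kernel Kernel used for euthymic patients.
#' @param euthymia_prob Probability a patient stays euthymic throughout.
#' @param retention_prob Probability a patient completes follow-up.
#' @param dropout_severity_weight Log-odds shift in dropout per unit of
#'   baseline severity above the cohort mean. The default 0 makes attrition
#'   missing-completely-at-random (followed and lost patients had
#'   indistinguishable severity in the source cohort); nonzero values
#'   support sensitivity analyses with severity-dependent dropout.
#' @param rejection_sampling If `TRUE` (default) a patient's profile is
#'   resampled until its computed severity lands inside the intended stage's
#'   interval, making the generated stage label exact by construction.
#' @param max_tries Resampling bound per patient before erroring.
#' @param registry,cutoffs Transform registry and stage cutoffs used for the
#'   rejection check.
#' @param gaf_params,drug_params External-validator distributions.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_baseline = 129,
                          stage_dist = c(0.109, 0.155, 0.473, 0.186, 0.078),
                          stage_params = default_stage_params(),
                          kernel = default_transition_kernel(),
                          euthymic_kernel = default_euthymic_kernel(),
                          euthymia_prob = 0.322,
                          retention_prob = 0.576,
                          dropout_severity_weight = 0,
                          rejection_sampling = TRUE,
                          max_tries = 1000,
                          registry = default_transform_registry(),
                          cutoffs = stage_cutoffs(),
                          gaf_params = default_gaf_params(),
                          drug_params = default_drug_params(),
                          seed = NULL) {
  stage_dist <- stage_dist / sum(stage_dist)
  if (n_baseline < 1) stop("n_baseline must be at least 1.", call. = FALSE)
  if (length(stage_dist) != 5 || any(stage_dist < 0)) {
    stop("stage_dist must be five non-negative probabilities.", call. = FALSE)
  }
  check_kernel <- function(k, name) {
    if (!is.matrix(k) || any(dim(k) != 5) || any(k < 0) ||
        any(abs(rowSums(k) - 1) > 1e-9)) {
      stop(name, " must be a 5x5 row-stochastic matrix.", call. = FALSE)
    }
  }
  check_kernel(kernel, "kernel")
  check_kernel(euthymic_kernel, "euthymic_kernel")
  for (p in c(euthymia_prob, retention_prob)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1].", call. = FALSE)
  }
  structure(list(
    n_baseline = n_baseline, stage_dist = stage_dist,
    stage_params = stage_params, kernel = kernel,
    euthymic_kernel = euthymic_kernel, euthymia_prob = euthymia_prob,
    retention_prob = retention_prob,
    dropout_severity_weight = dropout_severity_weight,
    rejection_sampling = rejection_sampling, max_tries = max_tries,
    registry = registry, cutoffs = cutoffs,
    gaf_params = gaf_params, drug_params = drug_params, seed = seed
  ), class = "cohort_config")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  # inverse-CDF truncated normal
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}

rcount <- function(n, mean, sd) {
  if (mean <= 0) return(rep(0L, n))
  if (sd^2 > mean) {
    size <- mean^2 / (sd^2 - mean)
    stats::rnbinom(n, size = size, mu = mean)
  } else {
    stats::rpois(n, mean)
  }
}

sample_profiler <- function(n, spec, stage) {
  switch(spec$kind,
    count = rcount(n, spec$mean[stage], spec$sd[stage]),
    binary = stats::rbinom(n, 1, spec$p[stage]),
    truncnorm = rtruncnorm(n, spec$mean[stage], spec$sd[stage], spec$lo, spec$hi),
    truncnorm_int = pmin(pmax(round(
      rtruncnorm(n, spec$mean[stage], spec$sd[stage], spec$lo, spec$hi)),
      spec$lo), spec$hi),
    normal = stats::rnorm(n, spec$mean[stage], spec$sd[stage]),
    categorical = sample(spec$levels, n, replace = TRUE,
                         prob = spec$probs[stage, ]),
    stop("unknown profiler distribution kind: ", spec$kind, call. = FALSE)
  )
}

sample_stage_profiles <- function(n, stage, config) {
  out <- tibble::tibble(.rows = n)
  for (p in profiler_names()) {
    out[[p]] <- sample_profiler(n, config$stage_params[[p]], stage)
  }
  out
}

# Draw n profiles for one stage, resampling (when enabled) the rows whose
# severity falls outside the stage's interval until all match.
draw_profiles <- function(n, stage, config) {
  profiles <- sample_stage_profiles(n, stage, config)
  if (!config$rejection_sampling || n == 0) return(profiles)
  for (try in seq_len(config$max_tries)) {
    scored <- score_cohort(profiles, config$registry, config$cutoffs)
    bad <- which(scored$stage != stage)
    if (length(bad) == 0) return(profiles)
    profiles[bad, ] <- sample_stage_profiles(length(bad), stage, config)
  }
  stop("rejection sampling failed to hit stage ", stage, " within ",
       config$max_tries, " tries.", call. = FALSE)
}

with_config_seed <- function(config, offset, code) {
  if (is.null(config$seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + offset)
  force(code)
}

#' Generate a synthetic baseline cohort
#'
#' Samples each patient's intended stage from the baseline stage
#' distribution, then the twelve profilers from that stage's distributions.
#' With rejection sampling on (the default), profiles are redrawn until the
#' computed severity lands in the intended stage, so the generated
#' `true_stage` label always agrees with [score_cohort()].
#'
#' @param config A [cohort_config()].
#' @return A tibble: `patient_id`, `timepoint = "baseline"`, `true_stage`,
#'   `euthymic_throughout`, the 12 raw profiler columns.
#' @examples
#' generate_baseline(cohort_config(n_baseline = 10, seed = 42))
#' @export
generate_baseline <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_config_seed(config, 0, {
    stage <- sample(1:5, config$n_baseline, replace = TRUE,
                    prob = config$stage_dist)
    euthymic <- stats::rbinom(config$n_baseline, 1, config$euthymia_prob)
    profiles <- vector("list", 5)
    for (s in 1:5) {
      profiles[[s]] <- draw_profiles(sum(stage == s), s, config)
    }
    out <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(config$n_baseline)),
      timepoint = "baseline",
      true_stage = stage,
      euthymic_throughout = euthymic
    )
    # bind_rows(profiles) lists patients sorted by stage (stable order);
    # order(order(stage)) is the inverse permutation back to patient order
    prof_all <- dplyr::bind_rows(profiles)[order(order(stage)), ]
    dplyr::bind_cols(out, prof_all)
  })
}

#' Evolve a baseline cohort to 3-year follow-up
#'
#' Each patient's follow-up stage is drawn from the kernel row of their
#' baseline stage (euthymic patients use the euthymic kernel, which is
#' biased toward staying or regressing); follow-up profilers are then drawn
#' from the target stage's distributions (with the same rejection rule); and
#' retention filtering keeps each patient with the configured probability.
#'
#' @param baseline A cohort from [generate_baseline()] (or schema-compatible,
#'   with `patient_id`, `true_stage`, `euthymic_throughout`).
#' @param config The [cohort_config()] used at baseline.
#' @return A list: `followup` (tibble like the baseline, only completers)
#'   and `pairs` (tibble of `patient_id`, `baseline_stage`,
#'   `followup_stage`, `euthymic_throughout`).
#' @export
evolve_cohort <- function(baseline, config) {
  stopifnot(inherits(config, "cohort_config"))
  needed <- c("patient_id", "true_stage", "euthymic_throughout")
  if (!all(needed %in% names(baseline))) {
    stop("baseline must carry ", paste(needed, collapse = ", "), call. = FALSE)
  }
  with_config_seed(config, 1, {
    n <- nrow(baseline)
    p_keep <- rep(config$retention_prob, n)
    w <- config$dropout_severity_weight %||% 0
    if (w != 0) {
      sev <- score_cohort(baseline, config$registry, config$cutoffs)$severity
      p_keep <- stats::plogis(stats::qlogis(config$retention_prob) -
                                w * (sev - mean(sev, na.rm = TRUE)))
    }
    retained <- stats::runif(n) < p_keep
    fu_stage <- integer(n)
    for (i in seq_len(n)) {
      k <- if (baseline$euthymic_throughout[i] == 1) config$euthymic_kernel
           else config$kernel
      fu_stage[i] <- sample(1:5, 1, prob = k[baseline$true_stage[i], ])
    }
    keep <- which(retained)
    profiles <- vector("list", 5)
    for (s in 1:5) {
      profiles[[s]] <- draw_profiles(sum(fu_stage[keep] == s), s, config)
    }
    prof_all <- dplyr::bind_rows(profiles)[order(order(fu_stage[keep])), ]
    followup <- dplyr::bind_cols(
      tibble::tibble(
        patient_id = baseline$patient_id[keep],
        timepoint = "followup",
        true_stage = fu_stage[keep],
        euthymic_throughout = baseline$euthymic_throughout[keep]
      ),
      prof_all
    )
    pairs <- tibble::tibble(
      patient_id = baseline$patient_id[keep],
      baseline_stage = baseline$true_stage[keep],
      followup_stage = fu_stage[keep],
      euthymic_throughout = baseline$euthymic_throughout[keep]
    )
    list(followup = followup, pairs = pairs)
  })
}

#' Attach external validators to a staged cohort
#'
#' Adds GAF (truncated normal per stage, bounded 1-100) and drug-pattern
#' columns (prescribed-drug-count category plus antipsychotic,
#' antidepressant and benzodiazepine flags, Bernoulli per stage).
#'
#' @param cohort A cohort with a `true_stage` (or `stage`) column.
#' @param config A [cohort_config()].
#' @return The cohort with `gaf`, `n_drugs_cat`, `antipsychotics`,
#'   `antidepressants`, `benzodiazepines` columns appended.
#' @export
attach_external_validators <- function(cohort, config = cohort_config()) {
  stage <- cohort$true_stage %||% cohort$stage
  if (is.null(stage)) stop("cohort needs a stage column.", call. = FALSE)
  dp <- config$drug_params
  if (any(abs(colSums(dp$n_drugs_cat) - 1) > 1e-9)) {
    stop("drug-count category probabilities must sum to 1 per stage.",
         call. = FALSE)
  }
  offset <- if (identical(unique(cohort$timepoint), "followup")) 3 else 2
  with_config_seed(config, offset, {
    g <- config$gaf_params
    out <- tibble::as_tibble(cohort)
    out$gaf <- round(rtruncnorm(nrow(out), g$mean[stage], g$sd[stage],
                                g$lo, g$hi))
    out$n_drugs_cat <- vapply(stage, function(s) {
      sample(rownames(dp$n_drugs_cat), 1, prob = dp$n_drugs_cat[, s])
    }, character(1))
    for (drug in c("antipsychotics", "antidepressants", "benzodiazepines")) {
      out[[drug]] <- stats::rbinom(nrow(out), 1, dp[[drug]][stage])
    }
    out
  })
}

#' Simulate a full longitudinal cohort
#'
#' Convenience wrapper: baseline generation, evolution to follow-up, and
#' external validators at both timepoints.
#'
#' @param config A [cohort_config()].
#' @return A list: `baseline`, `followup`, `pairs`.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_baseline = 40, seed = 7))
#' transition_matrix(sim$pairs)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  baseline <- generate_baseline(config)
  evolved <- evolve_cohort(baseline, config)
  list(
    baseline = attach_external_validators(baseline, config),
    followup = attach_external_validators(evolved$followup, config),
    pairs = evolved$pairs
  )
}
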