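#' Canonical profiler names and life domains
#'
#' The staging model scores twelve patient-level "profilers" drawn from five
#' life domains: clinical course of the disorder, physical health, cognition,
#' real-world functioning, and health-related quality of life.
#'
#' @return A tibble with one row per profiler: `profiler`, `life_domain`,
#'   and `type` (`count`, `binary`, `ordinal`, `scale`, `bmi`, or `z`).
#' @examples
#' profiler_info()
#' @export
profiler_info <- function() {
  tibble::tribble(
    ~profiler,      ~life_domain,       ~type,
    "hosp_n",       "bipolar_disorder", "count",
    "suic_att_n",   "bipolar_disorder", "count",
    "com_pd",       "bipolar_disorder", "binary",
    "bmi",          "physical_health",  "bmi",
    "mets",         "physical_health",  "binary",
    "illness_n",    "physical_health",  "count",
    "scip_cat",     "cognition",        "ordinal",
    "pd_x_bd",      "functioning",      "binary",
    "fast_total",   "functioning",      "scale",
    "fast_leisure", "functioning",      "scale",
    "sf_pf",        "qol",              "z",
    "sf_mh",        "qol",              "z"
  )
}

#' @rdname profiler_info
#' @export
profiler_names <- function() profiler_info()$profiler

scip_levels <- c("none", "mild", "moderate", "severe")

#' Transform a count profiler to the unit interval by capping
#'
#' Counts (hospitalizations, suicide attempts, comorbid physical illnesses)
#' are divided by a cap, with counts at or beyond the cap saturating at 1.
#'
#' @param count Non-negative integer count(s).
#' @param cap Positive integer saturation point.
#' @return `min(count, cap) / cap`, a value in \[0, 1\]. `NA` is propagated.
#' @examples
#' transform_capped_count(0:8, cap = 6)
#' @export
transform_capped_count <- function(count, cap) {
  if (length(cap) != 1L || is.na(cap) || cap < 1) {
    stop("`cap` must be a single positive integer.", call. = FALSE)
  }
  if (any(count < 0, na.rm = TRUE)) {
    stop("counts must be non-negative.", call. = FALSE)
  }
  pmin(count, cap) / cap
}

#' Transform a binary profiler
#'
#' Binary flags (comorbid personality disorder, metabolic syndrome,
#' permanent disability due to the disorder) enter the severity score
#' unchanged, so the transformed cohort mean of a binary profiler equals its
#' prevalence exactly.
#'
#' @param flag 0/1 flag(s); logicals are accepted.
#' @return The flag as a number in {0, 1}. `NA` is propagated.
#' @export
transform_binary <- function(flag) {
  flag <- as.numeric(flag)
  ok <- is.na(flag) | flag %in% c(0, 1)
  if (!all(ok)) stop("binary profiler values must be 0 or 1.", call. = FALSE)
  flag
}

#' Linearly rescale a bounded scale score to the unit interval
#'
#' Used for the FAST total (0-72) and FAST leisure subscale (0-6), where
#' higher raw scores mean worse functioning.
#'
#' @param score Numeric score(s).
#' @param lo,hi Instrument range; `lo < hi`.
#' @return `(score - lo) / (hi - lo)` clipped to \[0, 1\].
#' @examples
#' transform_linear_rescale(26.8, 0, 72)
#' @export
transform_linear_rescale <- function(score, lo, hi) {
  if (!(lo < hi)) stop("`lo` must be strictly below `hi`.", call. = FALSE)
  pmin(pmax((score - lo) / (hi - lo), 0), 1)
}

#' Map an ordinal category to the unit interval
#'
#' Default map for the SCIP cognitive-impairment category:
#' none 0, mild 1/3, moderate 2/3, severe 1.
#'
#' @param category Character or factor level(s).
#' @param level_map Named numeric vector, ordered from least to most severe;
#'   values must be non-decreasing and lie in \[0, 1\].
#' @return The mapped value(s). Unknown categories are an error.
#' @export
transform_ordinal <- function(category,
                              level_map = c(none = 0, mild = 1 / 3,
                                            moderate = 2 / 3, severe = 1)) {
  if (is.null(names(level_map)) || is.unsorted(level_map) ||
      any(level_map < 0 | level_map > 1)) {
    stop("`level_map` must be a named, non-decreasing map into [0, 1].",
         call. = FALSE)
  }
  category <- as.character(category)
  unknown <- setdiff(stats::na.omit(unique(category)), names(level_map))
  if (length(unknown) > 0) {
    stop("unknown ordinal categor", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(level_map[category])
}

#' Transform an SF-36 z-score to a severity contribution
#'
#' SF-36 scale scores enter as z-scores where higher means better health, so
#' the map is decreasing: the best health (`z_best`) contributes 0 severity
#' and the worst (`z_worst`) contributes 1, linearly in between and clipped
#' outside.
#'
#' @param z Numeric z-score(s).
#' @param z_best,z_worst Endpoints of the linear ramp (defaults +3 / -3).
#' @return `(z_best - z) / (z_best - z_worst)` clipped to \[0, 1\].
#' @export
transform_z_linear <- function(z, z_best = 3, z_worst = -3) {
  if (z_best == z_worst) {
    stop("`z_best` and `z_worst` must differ.", call. = FALSE)
  }
  pmin(pmax((z_best - z) / (z_best - z_worst), 0), 1)
}

#' Transform body mass index through a category step map
#'
#' The default map follows the WHO categories: BMI below 25 contributes 0,
#' overweight (25 to <30) contributes 0.5, obesity (30 and over) contributes 1.
#'
#' @param bmi Positive BMI value(s) in kg/m^2.
#' @param breaks Increasing interior break points.
#' @param values Value per category (`length(breaks) + 1`), non-decreasing
#'   within \[0, 1\].
#' @return The step-map value(s).
#' @export
transform_bmi <- function(bmi, breaks = c(25, 30), values = c(0, 0.5, 1)) {
  if (any(bmi <= 0, na.rm = TRUE)) stop("BMI must be positive.", call. = FALSE)
  if (is.unsorted(breaks, strictly = TRUE) || length(values) != length(breaks) + 1L ||
      is.unsorted(values) || any(values < 0 | values > 1)) {
    stop("invalid BMI category map.", call. = FALSE)
  }
  values[findInterval(bmi, breaks) + 1L]
}

#' Default transform registry
#'
#' One row per profiler giving the transform kind and its parameters. The
#' defaults are: counts capped at 6 (hospitalizations, suicide attempts) or 4
#' (physical illnesses); binaries passed through; FAST total rescaled over
#' 0-72 and FAST leisure over 0-6; SCIP mapped over equally spaced quartile
#' values; BMI through the WHO step map; SF-36 z-scores linear and reversed
#' on \[-3, 3\]. Every entry can be overridden, and a registry can be stored
#' as YAML with [write_transform_registry()].
#'
#' @return A tibble with columns `profiler`, `kind`, and `params`
#'   (a list-column of parameter lists).
#' @examples
#' default_transform_registry()
#' @export
default_transform_registry <- function() {
  tibble::tibble(
    profiler = profiler_names(),
    kind = c("capped_count", "capped_count", "binary", "categorical_bmi",
             "binary", "capped_count", "ordinal_map", "binary",
             "linear_rescale", "linear_rescale", "z_linear_clip",
             "z_linear_clip"),
    params = list(
      list(cap = 6), list(cap = 6), list(), list(breaks = c(25, 30), values = c(0, 0.5, 1)),
      list(), list(cap = 4),
      list(level_map = c(none = 0, mild = 1 / 3, moderate = 2 / 3, severe = 1)),
      list(),
      list(lo = 0, hi = 72), list(lo = 0, hi = 6),
      list(z_best = 3, z_worst = -3), list(z_best = 3, z_worst = -3)
    )
  )
}

apply_transform <- function(x, kind, params) {
  switch(kind,
    capped_count   = transform_capped_count(x, params$cap),
    binary         = transform_binary(x),
    ordinal_map    = transform_ordinal(x, params$level_map),
    linear_rescale = transform_linear_rescale(x, params$lo, params$hi),
    categorical_bmi = transform_bmi(x, params$breaks, params$values),
    z_linear_clip  = transform_z_linear(x, params$z_best, params$z_worst),
    stop("unknown transform kind: ", kind, call. = FALSE)
  )
}

check_registry <- function(registry) {
  needed <- profiler_names()
  if (!all(c("profiler", "kind", "params") %in% names(registry))) {
    stop("a transform registry needs columns profiler, kind, params.",
         call. = FALSE)
  }
  missing <- setdiff(needed, registry$profiler)
  if (length(missing) > 0) {
    stop("transform registry is missing profiler(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(registry$profiler)) {
    stop("transform registry lists a profiler more than once.", call. = FALSE)
  }
  invisible(registry)
}

#' Map raw profiler columns to the unit interval
#'
#' Applies the registry transform to each of the twelve profiler columns of a
#' patient table. Non-profiler columns (identifiers, timepoint, validators)
#' pass through untouched. Missing raw values stay missing; they are never
#' silently treated as zero.
#'
#' @param data A data frame with the twelve raw profiler columns (see
#'   [profiler_info()] for the canonical names).
#' @param registry A transform registry; see [default_transform_registry()].
#' @return A tibble of the same rows in which each profiler column holds its
#'   transformed value in \[0, 1\].
#' @examples
#' raw <- tibble::tibble(
#'   hosp_n = 2, suic_att_n = 0, com_pd = 1, bmi = 27.4, mets = 0,
#'   illness_n = 1, scip_cat = "mild", pd_x_bd = 0, fast_total = 20,
#'   fast_leisure = 3, sf_pf = -0.5, sf_mh = -1.1
#' )
#' transform_profilers(raw)
#' @export
transform_profilers <- function(data, registry = default_transform_registry()) {
  check_registry(registry)
  missing_cols <- setdiff(profiler_names(), names(data))
  if (length(missing_cols) > 0) {
    stop("data is missing profiler column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(registry))) {
    p <- registry$profiler[i]
    if (!p %in% profiler_names()) next
    out[[p]] <- apply_transform(out[[p]], registry$kind[i], registry$params[[i]])
  }
  out
}
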