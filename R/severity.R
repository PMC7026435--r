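#' Stage cutoffs on the severity axis
#'
#' Four strictly increasing interior boundaries partition the 0-10 severity
#' axis into five stages. Stage 1 covers `[0, c1]`, each interior stage s
#' covers `(c_{s-1}, c_s]`, and stage 5 covers `(c4, 10]`. The defaults
#' (1.70, 2.50, 4.50, 6.10) are the published percentile-derived boundaries,
#' under which a score of exactly 6.10 is stage 4 and 6.11 or more is stage 5.
#'
#' @param cutoffs Numeric vector of four strictly increasing values in (0, 10).
#' @return A `stage_cutoffs` object.
#' @examples
#' stage_cutoffs()
#' @export
stage_cutoffs <- function(cutoffs = c(1.70, 2.50, 4.50, 6.10)) {
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) != 4L || anyNA(cutoffs)) {
    stop("`cutoffs` must be four numeric boundaries.", call. = FALSE)
  }
  if (is.unsorted(cutoffs, strictly = TRUE) ||
      cutoffs[1] <= 0 || cutoffs[4] >= 10) {
    stop("cutoffs must be strictly increasing within (0, 10).", call. = FALSE)
  }
  structure(cutoffs, class = "stage_cutoffs")
}

#' @export
print.stage_cutoffs <- function(x, ...) {
  cat("Stage cutoffs (stage s = (c[s-1], c[s]], stage 1 from 0):\n")
  cat(" ", paste(format(unclass(x)), collapse = " | "), "\n")
  invisible(x)
}

#' Global severity score
#'
#' The severity score is 10/12 times the sum of the twelve unit-interval
#' profilers, so all profilers carry the same weight and the score ranges
#' from 0 (no burden on any profiler) to 10 (maximal burden on all twelve).
#'
#' @param profile A named numeric vector, or a data frame of transformed
#'   profiles (one row per patient), holding all twelve profiler values in
#'   \[0, 1\] under their canonical names.
#' @return A numeric severity score per profile, in \[0, 10\].
#' @examples
#' severity_score(stats::setNames(rep(1, 12), profiler_names()))
#' @export
severity_score <- function(profile) {
  if (is.data.frame(profile)) {
    missing_cols <- setdiff(profiler_names(), names(profile))
    if (length(missing_cols) > 0) {
      stop("missing profiler(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    vals <- as.matrix(profile[profiler_names()])
  } else {
    missing_cols <- setdiff(profiler_names(), names(profile))
    if (length(missing_cols) > 0) {
      stop("missing profiler(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    vals <- matrix(profile[profiler_names()], nrow = 1)
  }
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
    stop("profiler values must lie in [0, 1]; transform raw values first.",
         call. = FALSE)
  }
  # 10/12 * sum over the 12 profilers, written as 10 * mean so the extremes
  # evaluate to exactly 0 and 10 in floating point
  as.numeric(10 * rowMeans(vals))
}

#' Assign severity scores to stages
#'
#' @param severity Numeric severity score(s) in \[0, 10\].
#' @param cutoffs A [stage_cutoffs()] object (defaults to the published
#'   boundaries).
#' @return Integer stage(s) 1-5; `NA` severity gives `NA` stage.
#' @examples
#' assign_stage(c(0, 1.7, 1.71, 4.5, 6.10, 6.11, 10))
#' @export
assign_stage <- function(severity, cutoffs = stage_cutoffs()) {
  if (!inherits(cutoffs, "stage_cutoffs")) cutoffs <- stage_cutoffs(cutoffs)
  if (any(severity < 0 | severity > 10, na.rm = TRUE)) {
    stop("severity must lie in [0, 10].", call. = FALSE)
  }
  out <- rep(NA_integer_, length(severity))
  ok <- !is.na(severity)
  # stage = 1 + number of boundaries strictly below the score, which makes
  # each boundary itself belong to the lower stage
  out[ok] <- 1L + rowSums(outer(severity[ok], unclass(cutoffs), ">"))
  out
}

#' Calibrate stage cutoffs from a severity sample
#'
#' Recomputes the four interior boundaries as empirical percentiles of a
#' severity sample, using the linear-interpolation percentile definition
#' (`stats::quantile` type 7).
#'
#' @param severities Numeric vector of at least 20 severity scores.
#' @param percentiles Four strictly increasing percentiles in (0, 100);
#'   defaults to the model's 5th, 25th, 50th and 75th.
#' @return A [stage_cutoffs()] object.
#' @examples
#' calibrate_cutoffs(seq(0, 10, by = 0.1))
#' @export
calibrate_cutoffs <- function(severities, percentiles = c(5, 25, 50, 75)) {
  severities <- severities[!is.na(severities)]
  if (length(severities) < 20) {
    stop("need at least 20 severity values to calibrate cutoffs.",
         call. = FALSE)
  }
  if (length(percentiles) != 4L || is.unsorted(percentiles, strictly = TRUE) ||
      any(percentiles <= 0 | percentiles >= 100)) {
    stop("`percentiles` must be four strictly increasing values in (0, 100).",
         call. = FALSE)
  }
  q <- unname(stats::quantile(severities, percentiles / 100, type = 7))
  if (any(diff(q) <= 0)) {
    stop("calibration failed: tied percentiles cannot partition the axis.",
         call. = FALSE)
  }
  stage_cutoffs(q)
}

#' Score and stage a cohort
#'
#' Transforms the raw profiler columns, computes each patient's global
#' severity score, and assigns a stage. Rows with a missing profiler get
#' `NA` severity and stage (missingness is surfaced, never zero-filled).
#'
#' @param data A data frame of raw profiler columns, typically with
#'   `patient_id` and `timepoint` columns as well.
#' @param registry Transform registry ([default_transform_registry()]).
#' @param cutoffs A [stage_cutoffs()] object.
#' @return The input as a tibble with `severity` and `stage` columns
#'   appended, carrying the cutoffs used as an attribute.
#' @examples
#' cohort <- generate_baseline(cohort_config(n_baseline = 25, seed = 1))
#' dplyr::count(score_cohort(cohort), stage)
#' @export
score_cohort <- function(data, registry = default_transform_registry(),
                         cutoffs = stage_cutoffs()) {
  if (nrow(data) == 0) stop("empty cohort.", call. = FALSE)
  transformed <- transform_profilers(data, registry)
  vals <- as.matrix(transformed[profiler_names()])
  severity <- ifelse(rowSums(is.na(vals)) > 0, NA_real_,
                     10 * rowMeans(vals, na.rm = TRUE))
  out <- tibble::as_tibble(data)
  out$severity <- as.numeric(severity)
  out$stage <- assign_stage(out$severity, cutoffs)
  attr(out, "cutoffs") <- cutoffs
  out
}

#' Summarise a scored cohort
#'
#' @param scored A cohort scored by [score_cohort()].
#' @return A list with `severity` (one-row tibble: n, mean, sd, min, max) and
#'   `stages` (per-stage counts and percentages).
#' @export
summarise_cohort <- function(scored) {
  if (!"severity" %in% names(scored)) {
    stop("`scored` must come from score_cohort().", call. = FALSE)
  }
  sev <- scored$severity[!is.na(scored$severity)]
  stages <- tibble::tibble(stage = factor(scored$stage, levels = 1:5)) |>
    dplyr::count(.data$stage, .drop = FALSE) |>
    dplyr::mutate(stage = as.integer(as.character(.data$stage)),
                  pct = 100 * .data$n / sum(.data$n))
  list(
    severity = tibble::tibble(
      n = length(sev), mean = mean(sev), sd = stats::sd(sev),
      min = min(sev), max = max(sev)
    ),
    stages = stages
  )
}

#' Severity distribution plot for a scored cohort
#'
#' Histogram of severity scores with the stage boundaries overlaid.
#'
#' @param scored A cohort scored by [score_cohort()].
#' @param binwidth Histogram bin width on the severity axis.
#' @return A ggplot object.
#' @export
plot_severity_distribution <- function(scored, binwidth = 0.5) {
  cutoffs <- attr(scored, "cutoffs") %||% stage_cutoffs()
  ggplot2::ggplot(scored, ggplot2::aes(x = .data$severity)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = unclass(cutoffs), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_continuous(limits = c(0, 10)) +
    ggplot2::labs(x = "Global severity score (0-10)", y = "Patients",
                  title = "Severity distribution with stage boundaries") +
    ggplot2::theme_minimal()
}
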