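#' Pearson chi-square test of independence
#'
#' Classical Pearson statistic on a contingency table of counts, with no
#' continuity correction and the asymptotic reference distribution (matching
#' routine clinical reporting). Rows or columns with a zero marginal are
#' dropped with a warning before the statistic is computed; a warning is also
#' attached when any expected count falls below 5.
#'
#' @param table A matrix (or table) of non-negative integer counts, at least
#'   2x2 after zero-marginal rows/columns are dropped.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, and
#'   `min_expected`.
#' @examples
#' yes <- c(7, 8, 37, 16, 8); n <- c(14, 20, 61, 24, 10)
#' chi_square_independence(rbind(yes, no = n - yes))
#' @export
chi_square_independence <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || anyNA(m)) {
    stop("contingency table must hold non-negative counts.", call. = FALSE)
  }
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping row(s)/column(s) with zero marginal totals.",
            call. = FALSE)
    m <- m[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least 2 rows and 2 columns with positive marginals.",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  min_e <- min(res$expected)
  if (min_e < 5) {
    warning("expected count below 5; asymptotic p-value may be inaccurate.",
            call. = FALSE)
  }
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value),
    min_expected = min_e
  )
}

as_group_list <- function(data, value, group) {
  if (is.list(data) && !is.data.frame(data)) return(data)
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  split(dplyr::pull(data, !!value), dplyr::pull(data, !!group))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test), reported
#' with between and within degrees of freedom `(k - 1, N - k)`.
#'
#' @param data A data frame, or a list of numeric vectors (one per group).
#' @param value,group When `data` is a data frame: the value and grouping
#'   columns (tidy evaluation).
#' @return A one-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`.
#' @examples
#' oneway_anova(list(rnorm(10), rnorm(10, 1), rnorm(10, 2)))
#' @export
oneway_anova <- function(data, value, group) {
  groups <- as_group_list(data, {{ value }}, {{ group }})
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least two groups.", call. = FALSE)
  if (any(lengths(groups) < 2)) {
    stop("every group needs at least two observations.", call. = FALSE)
  }
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(seq_along(groups), lengths(groups)))
  )
  if (all(df$y == df$y[1])) {
    # no variation anywhere: zero between-group signal by convention
    return(tibble::tibble(statistic = 0, df_between = length(groups) - 1,
                          df_within = nrow(df) - length(groups), p_value = 1))
  }
  fit <- stats::aov(y ~ g, data = df)
  tab <- summary(fit)[[1]]
  tibble::tibble(
    statistic = tab[["F value"]][1],
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2],
    p_value = tab[["Pr(>F)"]][1]
  )
}

#' Tukey honestly-significant-difference post-hoc comparisons
#'
#' All pairwise group-mean differences with studentized-range intervals at
#' the given family-wise level, as run after a one-way ANOVA.
#'
#' @inheritParams oneway_anova
#' @param alpha Family-wise error rate (default 0.05).
#' @return A tibble with one row per pair: `group_1`, `group_2`, `diff`,
#'   `conf_low`, `conf_high`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(data, value, group, alpha = 0.05) {
  groups <- as_group_list(data, {{ value }}, {{ group }})
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- seq_along(groups)
  }
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("need >= 2 groups with >= 2 observations each.", call. = FALSE)
  }
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  hsd <- stats::TukeyHSD(stats::aov(y ~ g, data = df), conf.level = 1 - alpha)$g
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  tibble::tibble(
    group_1 = vapply(pairs, `[`, "", 1),
    group_2 = vapply(pairs, `[`, "", 2),
    diff = hsd[, "diff"],
    conf_low = hsd[, "lwr"],
    conf_high = hsd[, "upr"],
    p_adj = hsd[, "p adj"],
    significant = hsd[, "p adj"] < alpha
  )
}

#' Paired t-test
#'
#' Classical paired-samples t statistic on within-patient differences,
#' `df = n - 1`.
#'
#' @param before,after Numeric vectors of equal length, paired by patient.
#'   Pairs with a missing value are dropped.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_diff`, `n`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) {
    stop("`before` and `after` must pair up (equal lengths).", call. = FALSE)
  }
  keep <- !(is.na(before) | is.na(after))
  before <- before[keep]; after <- after[keep]
  if (length(before) < 2) stop("need at least two complete pairs.", call. = FALSE)
  d <- after - before
  if (stats::sd(d) == 0) {
    # constant differences: t.test() refuses; report the limiting statistic
    return(tibble::tibble(
      statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
      df = length(d) - 1,
      p_value = if (mean(d) == 0) 1 else 0,
      mean_diff = mean(d), n = length(d)
    ))
  }
  res <- stats::t.test(after, before, paired = TRUE)
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value),
    mean_diff = unname(res$estimate),
    n = length(before)
  )
}

# Monotone-worsening rule for a sequence of per-stage means on the
# severity-oriented (transformed) scale: the stage-5 mean must exceed the
# stage-1 mean, and no consecutive dip may exceed `tol` times the span of
# the stage means. The relative dip absorbs sampling noise and small
# configured reversals without admitting profiles that trend the wrong way.
monotone_worsening <- function(stage_means, tol = 0.25) {
  m <- stage_means[!is.na(stage_means)]
  if (length(m) < 2) return(NA)
  span <- max(m) - min(m)
  if (span == 0) return(FALSE)
  dips <- pmax(-diff(m), 0)
  (m[length(m)] > m[1]) && all(dips <= tol * span)
}

#' Construct-validity battery for a staged cohort
#'
#' Stage-wise comparison of every profiler and the external validators:
#' one-way ANOVA across stages for continuous profilers (raw scale) and GAF,
#' Pearson chi-square for categorical profilers and any drug-pattern columns,
#' plus a monotone-worsening flag computed on the transformed per-stage
#' profiler means. No multiple-testing correction is applied; the report
#' carries raw p-values and says so.
#'
#' @param scored A cohort scored by [score_cohort()] (needs raw profiler
#'   columns and a `stage` column). Optional columns used when present:
#'   `gaf`, `n_drugs_cat`, `antipsychotics`, `antidepressants`,
#'   `benzodiazepines`.
#' @param registry Transform registry used for the monotone flag.
#' @param alpha Significance level for the `significant` flag.
#' @param dip_tol Tolerance of the monotone rule, as a fraction of the span
#'   of the per-stage means.
#' @return A `validity_report` object; see [tidy.validity_report()].
#' @export
build_validity_report <- function(scored,
                                  registry = default_transform_registry(),
                                  alpha = 0.05, dip_tol = 0.25) {
  if (!"stage" %in% names(scored)) {
    stop("every patient needs a stage; run score_cohort() first.",
         call. = FALSE)
  }
  scored <- dplyr::filter(scored, !is.na(.data$stage))
  stages_present <- sort(unique(scored$stage))
  notes <- character()
  if (length(stages_present) < 2) {
    notes <- c(notes, "fewer than two stages present: between-stage tests skipped")
  }
  small <- names(which(table(scored$stage) < 2))
  if (length(small) > 0) {
    warning("stage(s) with fewer than 2 patients excluded from ANOVA: ",
            paste(small, collapse = ", "), call. = FALSE)
  }

  info <- profiler_info()
  transformed <- transform_profilers(scored, registry)
  trans_means <- transformed |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(profiler_names()),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::arrange(.data$stage)

  test_one <- function(var, type) {
    continuous <- type %in% c("count", "scale", "z", "bmi")
    x <- scored[[var]]
    if (length(stages_present) < 2) {
      return(tibble::tibble(statistic = NA_real_, df = NA_real_,
                            df_within = NA_real_, p_value = NA_real_,
                            test = "skipped"))
    }
    if (continuous) {
      keep <- scored$stage %in% names(which(table(scored$stage) >= 2))
      res <- oneway_anova(split(x[keep], scored$stage[keep]))
      tibble::tibble(statistic = res$statistic, df = res$df_between,
                     df_within = res$df_within, p_value = res$p_value,
                     test = "anova")
    } else {
      tab <- table(as.character(x), scored$stage)
      if (nrow(tab) < 2) {
        # a single observed level carries no between-stage information
        return(tibble::tibble(statistic = NA_real_, df = NA_real_,
                              df_within = NA_real_, p_value = NA_real_,
                              test = "skipped"))
      }
      res <- suppressWarnings(chi_square_independence(tab))
      tibble::tibble(statistic = res$statistic, df = res$df,
                     df_within = NA_real_, p_value = res$p_value,
                     test = "chi_square")
    }
  }

  profiler_rows <- purrr::map2_dfr(info$profiler, info$type, function(p, ty) {
    res <- test_one(p, ty)
    dplyr::mutate(res,
      variable = p, life_domain = info$life_domain[info$profiler == p],
      role = "profiler",
      monotone_worsening = monotone_worsening(trans_means[[p]], dip_tol),
      .before = 1)
  })

  validator_rows <- NULL
  if ("gaf" %in% names(scored) && length(stages_present) >= 2) {
    res <- oneway_anova(split(scored$gaf, scored$stage))
    # GAF falls with severity, so "worsening" here means decreasing means
    validator_rows <- dplyr::bind_rows(validator_rows, tibble::tibble(
      variable = "gaf", life_domain = "external", role = "validator",
      monotone_worsening = monotone_worsening(
        -tapply(scored$gaf, scored$stage, mean, na.rm = TRUE), dip_tol),
      statistic = res$statistic, df = res$df_between,
      df_within = res$df_within, p_value = res$p_value, test = "anova"))
  }
  for (drug in intersect(c("n_drugs_cat", "antipsychotics", "antidepressants",
                           "benzodiazepines"), names(scored))) {
    if (length(stages_present) < 2) break
    tab <- table(as.character(scored[[drug]]), scored$stage)
    if (nrow(tab) < 2) next
    res <- suppressWarnings(chi_square_independence(tab))
    validator_rows <- dplyr::bind_rows(validator_rows, tibble::tibble(
      variable = drug, life_domain = "external", role = "validator",
      monotone_worsening = NA,
      statistic = res$statistic, df = res$df, df_within = NA_real_,
      p_value = res$p_value, test = "chi_square"))
  }

  rows <- dplyr::bind_rows(profiler_rows, validator_rows) |>
    dplyr::mutate(significant = .data$p_value < alpha)

  structure(
    list(tests = rows, stage_means = trans_means, alpha = alpha,
         dip_tol = dip_tol, notes = notes,
         correction = "none (raw p-values, uncorrected)"),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat("Construct-validity report (", x$correction, ")\n", sep = "")
  if (length(x$notes) > 0) cat("Notes:", paste(x$notes, collapse = "; "), "\n")
  print(x$tests, n = Inf)
  invisible(x)
}

#' Tidy a construct-validity report
#'
#' @param x A `validity_report`.
#' @param ... Unused.
#' @return A tibble with one row per tested variable: test type, statistic,
#'   degrees of freedom, p-value, monotone-worsening flag.
#' @method tidy validity_report
#' @export
tidy.validity_report <- function(x, ...) x$tests

#' One-line summary of a construct-validity report
#'
#' @param x A `validity_report`.
#' @param ... Unused.
#' @return A one-row tibble with counts of tested, significant, and
#'   monotone-worsening variables.
#' @method glance validity_report
#' @export
glance.validity_report <- function(x, ...) {
  prof <- dplyr::filter(x$tests, .data$role == "profiler")
  tibble::tibble(
    n_tested = nrow(x$tests),
    n_profilers = nrow(prof),
    n_significant = sum(x$tests$significant, na.rm = TRUE),
    n_monotone_worsening = sum(prof$monotone_worsening, na.rm = TRUE),
    alpha = x$alpha
  )
}

#' Stage-profile plot for a validity report
#'
#' Per-stage transformed means of each profiler, one line per profiler,
#' faceted by life domain. A valid staging model shows rising lines.
#'
#' @param report A `validity_report`.
#' @return A ggplot object.
#' @export
plot_stage_profiles <- function(report) {
  long <- report$stage_means |>
    tidyr::pivot_longer(-"stage", names_to = "profiler",
                        values_to = "mean_transformed") |>
    dplyr::left_join(profiler_info(), by = "profiler")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage,
                                     y = .data$mean_transformed,
                                     colour = .data$profiler)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~life_domain) +
    ggplot2::labs(x = "Stage", y = "Mean transformed profiler (0-1)",
                  title = "Profiler severity by stage") +
    ggplot2::theme_minimal()
}
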