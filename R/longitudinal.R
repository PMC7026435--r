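#' Stage-transition summary from baseline/follow-up pairs
#'
#' Cross-tabulates baseline against follow-up stages and aggregates the
#' shifts: the fraction of patients who stay at the same stage, move one
#' stage (either direction), or move two or more, plus the fractions who
#' progress (to a later stage) and regress.
#'
#' @param pairs A data frame with integer columns `baseline_stage` and
#'   `followup_stage` (both in 1-5); an optional `patient_id` column is
#'   carried through unchecked.
#' @return A `transition_summary` object: the 5x5 count matrix, row-wise
#'   conditional frequencies, and shift aggregates. See
#'   [tidy.transition_summary()] and [glance.transition_summary()].
#' @examples
#' pairs <- tibble::tibble(baseline_stage = c(1, 2, 3, 3),
#'                         followup_stage = c(2, 2, 3, 4))
#' transition_matrix(pairs)
#' @export
transition_matrix <- function(pairs) {
  if (nrow(pairs) == 0) stop("empty pair list.", call. = FALSE)
  b <- as.integer(pairs$baseline_stage)
  f <- as.integer(pairs$followup_stage)
  if (any(!b %in% 1:5) || any(!f %in% 1:5)) {
    stop("stages must lie in 1..5.", call. = FALSE)
  }
  counts <- table(factor(b, levels = 1:5), factor(f, levels = 1:5))
  counts <- matrix(as.integer(counts), 5, 5,
                   dimnames = list(baseline = 1:5, followup = 1:5))
  row_totals <- rowSums(counts)
  freq <- counts / ifelse(row_totals == 0, NA, row_totals)
  shift <- f - b
  n <- length(shift)
  aggregates <- tibble::tibble(
    n = n,
    same = mean(shift == 0),
    one_stage = mean(abs(shift) == 1),
    two_plus = mean(abs(shift) >= 2),
    progressed = mean(shift > 0),
    regressed = mean(shift < 0)
  )
  structure(
    list(counts = counts, freq = freq, aggregates = aggregates,
         empty_rows = which(row_totals == 0)),
    class = "transition_summary"
  )
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("Stage transitions (baseline rows -> follow-up columns), n =",
      x$aggregates$n, "\n")
  print(x$counts)
  a <- x$aggregates
  cat(sprintf(
    "same %.1f%% | +/-1 stage %.1f%% | +/-2+ %.1f%% | progressed %.1f%% | regressed %.1f%%\n",
    100 * a$same, 100 * a$one_stage, 100 * a$two_plus,
    100 * a$progressed, 100 * a$regressed))
  invisible(x)
}

#' Tidy a transition summary
#'
#' @param x A `transition_summary`.
#' @param ... Unused.
#' @return A long tibble: `baseline_stage`, `followup_stage`, `n`,
#'   `row_freq`.
#' @method tidy transition_summary
#' @export
tidy.transition_summary <- function(x, ...) {
  tibble::tibble(
    baseline_stage = rep(1:5, times = 5),
    followup_stage = rep(1:5, each = 5),
    n = as.vector(x$counts),
    row_freq = as.vector(x$freq)
  )
}

#' Shift aggregates of a transition summary
#'
#' @param x A `transition_summary`.
#' @param ... Unused.
#' @return A one-row tibble with `n` and the shift fractions.
#' @method glance transition_summary
#' @export
glance.transition_summary <- function(x, ...) x$aggregates

#' Transition-matrix heatmap
#'
#' @param summary A `transition_summary`.
#' @param what `"n"` for counts or `"row_freq"` for row-conditional
#'   frequencies.
#' @return A ggplot object.
#' @export
plot_transition_matrix <- function(summary, what = c("n", "row_freq")) {
  what <- match.arg(what)
  long <- tidy(summary)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$followup_stage,
                                     y = .data$baseline_stage,
                                     fill = .data[[what]])) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data[[what]]), "",
                     format(round(.data[[what]], 2)))), size = 3) +
    ggplot2::scale_y_reverse(breaks = 1:5) +
    ggplot2::scale_x_continuous(breaks = 1:5, position = "top") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 na.value = "grey90") +
    ggplot2::labs(x = "Follow-up stage", y = "Baseline stage") +
    ggplot2::theme_minimal()
}

#' Check that large stage shifts stay rare
#'
#' A staging model followed over a few years should see most patients stay
#' put or move one stage; this check passes when the fraction moving two or
#' more stages does not exceed the threshold (default 10%).
#'
#' @param summary A `transition_summary`.
#' @param max_big_shift_fraction Largest acceptable fraction of absolute
#'   shifts of two or more stages.
#' @return A one-row tibble: `pass`, `big_shift_fraction`, `threshold`, `n`.
#' @export
shift_expectations_check <- function(summary, max_big_shift_fraction = 0.10) {
  a <- summary$aggregates
  tibble::tibble(
    pass = a$two_plus <= max_big_shift_fraction,
    big_shift_fraction = a$two_plus,
    threshold = max_big_shift_fraction,
    n = a$n
  )
}

domain_composites <- function(data, registry) {
  transformed <- transform_profilers(data, registry)
  info <- profiler_info()
  out <- tibble::tibble(.rows = nrow(transformed))
  for (d in unique(info$life_domain)) {
    cols <- info$profiler[info$life_domain == d]
    out[[d]] <- rowMeans(as.matrix(transformed[cols]))
  }
  out
}

#' Longitudinal analysis of the sustained-euthymia subgroup
#'
#' Restricts the cohort to patients euthymic throughout follow-up, summarises
#' their stage transitions, and runs paired t-tests on each life-domain
#' composite (the mean of the domain's transformed profilers) between
#' baseline and follow-up — separately for the patients who remained at the
#' same stage and for those who regressed, where improvement on the
#' transformed scale shows up as a negative mean difference.
#'
#' @param pairs Stage pairs with a binary `euthymic_throughout` column and
#'   `patient_id`.
#' @param baseline,followup Raw-profiler tables with `patient_id`, covering
#'   the paired patients at each timepoint.
#' @param registry Transform registry for the domain composites.
#' @return A list: `summary` (the euthymic `transition_summary`, `NULL` when
#'   the subgroup is empty), `tests` (tibble of paired tests by subset and
#'   life domain), `notes`.
#' @export
euthymic_subgroup_analysis <- function(pairs, baseline, followup,
                                       registry = default_transform_registry()) {
  if (!"euthymic_throughout" %in% names(pairs)) {
    stop("`pairs` needs a euthymic_throughout column.", call. = FALSE)
  }
  eu <- dplyr::filter(pairs, .data$euthymic_throughout == 1)
  notes <- character()
  if (nrow(eu) == 0) {
    return(list(summary = NULL, tests = tibble::tibble(),
                notes = "euthymic subgroup is empty; all tests skipped"))
  }
  summary <- transition_matrix(eu)
  shift <- eu$followup_stage - eu$baseline_stage
  subsets <- list(remained_same = eu$patient_id[shift == 0],
                  regressed = eu$patient_id[shift < 0])

  composites_by_id <- function(tab) {
    tab <- dplyr::filter(tab, .data$patient_id %in% eu$patient_id)
    comp <- domain_composites(tab, registry)
    comp$patient_id <- tab$patient_id
    comp
  }
  bl <- composites_by_id(baseline)
  fu <- composites_by_id(followup)

  tests <- NULL
  for (s in names(subsets)) {
    ids <- subsets[[s]]
    if (length(ids) < 2) {
      notes <- c(notes, paste0(s, " subset has fewer than 2 patients; skipped"))
      next
    }
    for (d in unique(profiler_info()$life_domain)) {
      before <- bl[[d]][match(ids, bl$patient_id)]
      after <- fu[[d]][match(ids, fu$patient_id)]
      row <- paired_t(before, after)
      tests <- dplyr::bind_rows(
        tests, dplyr::mutate(row, subset = s, life_domain = d, .before = 1))
    }
  }
  list(summary = summary, tests = tests %||% tibble::tibble(), notes = notes)
}
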