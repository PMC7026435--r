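# Independent brute-force oracles used to cross-check the implementation.

# Pearson chi-square by explicit observed/expected double loop
oracle_chisq <- function(m) {
  m <- as.matrix(m)
  n <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / n
      stat <- stat + (m[i, j] - e)^2 / e
    }
  }
  list(statistic = unname(stat), df = (nrow(m) - 1) * (ncol(m) - 1))
}

# one-way ANOVA from first principles (sums of squares)
oracle_anova <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  list(F = (ssb / dfb) / (ssw / dfw), df_between = dfb, df_within = dfw)
}

# linear-interpolation percentile by direct sort-and-index
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# paired t as a one-sample t on the differences
oracle_paired_t <- function(before, after) {
  d <- after - before
  d <- d[!is.na(d)]
  d_bar <- mean(d)
  se <- sd(d) / sqrt(length(d))
  list(t = d_bar / se, df = length(d) - 1)
}

# two published 2x5 drug-use tables and the metabolic-syndrome table, with
# stage denominators reconstructed from the printed percentages
published_tables <- function() {
  list(
    antipsychotics = list(yes = c(7, 8, 37, 16, 8), n = c(14, 20, 61, 24, 10),
                          statistic = 5.925),
    antidepressants = list(yes = c(3, 6, 31, 11, 9), n = c(14, 20, 60, 24, 10),
                           statistic = 13.960),
    benzodiazepines = list(yes = c(3, 6, 31, 16, 8), n = c(14, 19, 61, 24, 10),
                           statistic = 13.430),
    mets = list(yes = c(0, 1, 27, 17, 6), n = c(14, 20, 61, 25, 9),
                statistic = 30.948)
  )
}

# transformed-profiler cohort means at each timepoint, as published
published_transformed_means <- function() {
  list(
    followup = c(0.19, 0.18, 0.18, 0.15, 0.39, 0.39, 0.47, 0.47, 0.37, 0.33,
                 0.53, 0.62),
    baseline = c(0.37, 0.15, 0.18, 0.32, 0.34, 0.26, 0.40, 0.46, 0.37, 0.40,
                 0.55, 0.55)
  )
}

# a minimal valid raw profile, overridable field by field
make_raw <- function(...) {
  base <- tibble::tibble(
    hosp_n = 0, suic_att_n = 0, com_pd = 0, bmi = 22, mets = 0,
    illness_n = 0, scip_cat = "none", pd_x_bd = 0, fast_total = 0,
    fast_leisure = 0, sf_pf = 3, sf_mh = 3
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

worst_raw <- function() {
  make_raw(hosp_n = 9, suic_att_n = 7, com_pd = 1, bmi = 35, mets = 1,
           illness_n = 6, scip_cat = "severe", pd_x_bd = 1, fast_total = 72,
           fast_leisure = 6, sf_pf = -3, sf_mh = -4)
}
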