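test_that("chi-square equals the brute-force O/E oracle on random tables", {
  set.seed(17)
  for (rep in 1:200) {
    r <- sample(2:4, 1); c <- sample(2:5, 1)
    m <- matrix(rpois(r * c, lambda = 8) + 1, nrow = r)
    got <- suppressWarnings(chi_square_independence(m))
    want <- oracle_chisq(m)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$df, want$df)
    # invariant to row/column permutation
    perm <- m[sample(nrow(m)), sample(ncol(m)), drop = FALSE]
    expect_equal(suppressWarnings(chi_square_independence(perm))$statistic,
                 got$statistic, tolerance = 1e-10)
  }
})

test_that("chi-square is zero for proportional rows and drops zero marginals", {
  prop <- rbind(c(10, 20, 30), c(5, 10, 15))
  expect_equal(suppressWarnings(chi_square_independence(prop))$statistic, 0,
               tolerance = 1e-12)
  withzero <- rbind(c(5, 0, 7), c(3, 0, 9), c(0, 0, 0))
  expect_warning(
    expect_warning(chi_square_independence(withzero), "zero marginal"),
    "expected count")
  res <- suppressWarnings(chi_square_independence(withzero))
  expect_equal(res$df, 1)
  expect_error(chi_square_independence(matrix(c(1, 2), 1)), "2 rows")
})

test_that("published drug-pattern and metabolic-syndrome statistics reproduce", {
  for (tab in published_tables()) {
    m <- rbind(yes = tab$yes, no = tab$n - tab$yes)
    got <- suppressWarnings(chi_square_independence(m))
    expect_equal(got$statistic, oracle_chisq(m)$statistic, tolerance = 1e-10)
    expect_equal(got$df, 4)
    expect_equal(got$statistic, tab$statistic, tolerance = 0.005)
  }
})

test_that("one-way ANOVA matches its oracle and classical identities", {
  set.seed(23)
  for (rep in 1:100) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(3:20, 1), mean = i / 2))
    got <- oneway_anova(groups)
    want <- oracle_anova(groups)
    expect_equal(got$statistic, want$F, tolerance = 1e-9)
    expect_equal(got$df_between, want$df_between)
    expect_equal(got$df_within, want$df_within)
    # location invariance and scale invariance of F
    shifted <- lapply(groups, `+`, 100)
    scaled <- lapply(groups, `*`, 3.7)
    expect_equal(oneway_anova(shifted)$statistic, got$statistic, tolerance = 1e-8)
    expect_equal(oneway_anova(scaled)$statistic, got$statistic, tolerance = 1e-8)
  }
  # two groups: F is the squared pooled t statistic
  a <- rnorm(12); b <- rnorm(15, 0.8)
  t2 <- stats::t.test(a, b, var.equal = TRUE)$statistic^2
  expect_equal(oneway_anova(list(a, b))$statistic, unname(t2), tolerance = 1e-10)
  # identical constant groups: zero F
  expect_equal(oneway_anova(list(c(1, 1, 1), c(1, 1, 1)))$statistic, 0)
  expect_error(oneway_anova(list(1:3)), "two groups")
  expect_error(oneway_anova(list(1:3, 5)), "at least two observations")
})

test_that("stage-wise FAST simulation concentrates F near the published value", {
  # five stage groups drawn at the published per-stage FAST means/SDs and
  # sizes; the Monte-Carlo distribution of F should bracket 37.0
  set.seed(31)
  means <- c(8.3, 15.6, 26.5, 38.0, 55.9)
  sds <- c(6.7, 10.2, 11.4, 11.7, 9.2)
  ns <- c(14, 20, 61, 24, 9)
  fs <- replicate(300, {
    groups <- Map(function(n, m, s) rnorm(n, m, s), ns, means, sds)
    oneway_anova(groups)$statistic
  })
  expect_gt(mean(fs), 25)
  expect_lt(mean(fs), 55)
  expect_true(stats::quantile(fs, 0.1) < 37.038 &&
                stats::quantile(fs, 0.9) > 37.038)
})

test_that("Tukey HSD flags shifted pairs and agrees with t at k = 2", {
  groups <- list(a = c(1, 2, 1.5, 2.2), b = c(1.1, 2.1, 1.4, 2.0))
  res <- tukey_hsd(groups)
  expect_false(any(res$significant))
  set.seed(37)
  a <- rnorm(20); b <- rnorm(20, 0.4)
  tk <- tukey_hsd(list(a = a, b = b))
  tt <- stats::t.test(b, a, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-8)
  # one shifted group among three: the shifted pairs get flagged far more
  # often than the null pair, at roughly the nominal alpha for the null
  hits_shift <- hits_null <- 0
  for (rep in 1:200) {
    g <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15, 2))
    res <- tukey_hsd(g)
    hits_null <- hits_null +
      res$significant[res$group_1 == "b" & res$group_2 == "a"]
    hits_shift <- hits_shift +
      res$significant[res$group_1 == "c" & res$group_2 == "a"]
  }
  expect_gt(hits_shift / 200, 0.95)
  expect_lt(hits_null / 200, 0.12)
})

test_that("paired t matches the one-sample oracle on differences", {
  set.seed(41)
  before <- rnorm(25); after <- before + rnorm(25, 0.3)
  got <- paired_t(before, after)
  want <- oracle_paired_t(before, after)
  expect_equal(got$statistic, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df)
  # identical samples: zero statistic; positive constant shift: positive t
  same <- rnorm(10)
  expect_equal(paired_t(same, same)$statistic, 0)
  shifted <- paired_t(before, before + 0.5 + rnorm(25, 0, 0.1))
  expect_gt(shifted$statistic, 0)
  expect_error(paired_t(1:3, 1:4), "equal lengths")
})

test_that("validity battery flags the expected profilers on a stage-structured cohort", {
  sim <- simulate_cohort(cohort_config(n_baseline = 1200, seed = 47))
  scored <- score_cohort(sim$followup)
  scored$gaf <- sim$followup$gaf
  scored$n_drugs_cat <- sim$followup$n_drugs_cat
  scored$antidepressants <- sim$followup$antidepressants
  report <- build_validity_report(scored)
  tests <- tidy(report)
  prof <- dplyr::filter(tests, role == "profiler")
  expect_equal(nrow(prof), 12)
  # continuous rows use ANOVA, categorical rows chi-square
  expect_true(all(prof$test[prof$variable %in%
    c("com_pd", "mets", "scip_cat", "pd_x_bd")] == "chi_square"))
  expect_true(all(prof$test[prof$variable %in%
    c("fast_total", "bmi", "sf_pf", "hosp_n")] == "anova"))
  # mental-health QoL is the sole non-worsening profiler
  expect_false(prof$monotone_worsening[prof$variable == "sf_mh"])
  expect_true(all(prof$monotone_worsening[prof$variable != "sf_mh"]))
  # external validators behave: GAF falls with stage, drugs differ by stage
  val <- dplyr::filter(tests, role == "validator")
  expect_true(val$monotone_worsening[val$variable == "gaf"])
  expect_true(all(val$significant))
  g <- glance(report)
  expect_equal(g$n_monotone_worsening, 11L)
})

test_that("randomly permuted stage labels kill the stage signal", {
  sim <- simulate_cohort(cohort_config(n_baseline = 400, seed = 53))
  scored <- score_cohort(sim$followup)
  set.seed(53)
  scored$stage <- sample(scored$stage)
  report <- suppressWarnings(build_validity_report(scored))
  tests <- dplyr::filter(tidy(report), role == "profiler")
  # significance collapses to near the nominal false-positive rate
  expect_lte(sum(tests$significant, na.rm = TRUE), 3)
  expect_lte(sum(tests$monotone_worsening, na.rm = TRUE), 3)
})

test_that("degenerate single-stage cohorts skip between-stage tests with notes", {
  cohort <- dplyr::bind_rows(replicate(6, make_raw(), simplify = FALSE))
  scored <- score_cohort(cohort)
  report <- build_validity_report(scored)
  expect_match(report$notes, "skipped")
  expect_true(all(tidy(report)$test == "skipped"))
})
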