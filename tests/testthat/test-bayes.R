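test_that("zero effects favor the null in every t family", {
  r0 <- bf_ttest_independent(m1 = 5, sd1 = 1, n1 = 36, m2 = 5, sd2 = 1,
                             n2 = 36)
  expect_lt(r0$bf10, 1)
  expect_equal(r0$bf10 * r0$bf01, 1)
  expect_lt(bf_ttest_paired(mean_diff = 0, sd_diff = 1, n = 20)$bf10, 1)
  expect_lt(bf_correlation(r = 0, n = 50)$bf10, 1)
})

test_that("the JZS integrator agrees with the delta-space oracle", {
  for (t in c(0, 0.5, 2, 2.5, 5)) {
    for (n in c(10, 20, 50)) {
      res <- bf_ttest_independent(m1 = t * sqrt(2 / n), sd1 = 1, n1 = n,
                                  m2 = 0, sd2 = 1, n2 = n)
      oracle <- oracle_bf_jzs(res$detail$t, res$detail$df, res$detail$neff)
      expect_equal(res$bf10, oracle, tolerance = 1e-6)
      resp <- bf_ttest_paired(mean_diff = t / sqrt(n), sd_diff = 1, n = n)
      oraclep <- oracle_bf_jzs(resp$detail$t, n - 1, n)
      expect_equal(resp$bf10, oraclep, tolerance = 1e-6)
    }
  }
})

test_that("t-family Bayes factors are even in t and increasing in |t|", {
  ns <- c(12, 40)
  ts <- c(0.5, 1, 1.5, 2, 3, 4)
  for (n in ns) {
    prev <- 0
    for (t in ts) {
      up <- bf_ttest_paired(mean_diff = t / sqrt(n), sd_diff = 1, n = n)
      dn <- bf_ttest_paired(mean_diff = -t / sqrt(n), sd_diff = 1, n = n)
      expect_equal(up$bf10, dn$bf10, tolerance = 1e-8)
      expect_gt(up$bf10, prev)
      prev <- up$bf10
    }
  }
})

test_that("summary-statistic and raw-data paths agree (sufficiency)", {
  set.seed(31)
  x <- rnorm(23, 1, 2); y <- rnorm(31, 0, 2)
  raw <- bf_ttest_independent(x = x, y = y)
  summ <- bf_ttest_independent(m1 = mean(x), sd1 = sd(x), n1 = length(x),
                               m2 = mean(y), sd2 = sd(y), n2 = length(y))
  expect_equal(raw$bf10, summ$bf10, tolerance = 1e-10)
  expect_false(raw$rounded_input)
  expect_true(summ$rounded_input)

  d <- rnorm(18, 0.4)
  rawp <- bf_ttest_paired(x = d)
  summp <- bf_ttest_paired(mean_diff = mean(d), sd_diff = sd(d),
                           n = length(d))
  expect_equal(rawp$bf10, summp$bf10, tolerance = 1e-10)

  a <- rnorm(25); b <- 0.5 * a + rnorm(25)
  rawc <- bf_correlation(x = a, y = b)
  summc <- bf_correlation(r = cor(a, b), n = 25)
  expect_equal(rawc$bf10, summc$bf10, tolerance = 1e-10)
})

test_that("degenerate inputs raise domain errors", {
  expect_error(bf_ttest_independent(m1 = 1, sd1 = 0, n1 = 10, m2 = 2,
                                    sd2 = 0, n2 = 10), "degenerate")
  expect_error(bf_ttest_paired(mean_diff = 1, sd_diff = 0, n = 10),
               "degenerate")
  expect_error(bf_correlation(r = 1, n = 20), "< 1")
  expect_error(bf_correlation(r = -1, n = 20), "< 1")
})

test_that("the correlation integrator agrees with the Euler-2F1 oracle", {
  for (r in c(-0.6, -0.2, 0, 0.105, 0.4, 0.8)) {
    for (n in c(10, 20, 46, 82)) {
      expect_equal(bf_correlation(r = r, n = n)$bf10,
                   oracle_bf_correlation(r, n), tolerance = 1e-6)
    }
  }
})

test_that("correlation Bayes factors are sign-symmetric, |r|-monotone, and fold one-sided", {
  for (n in c(15, 60)) {
    prev <- 0
    for (r in c(0.1, 0.3, 0.5, 0.7)) {
      bp <- bf_correlation(r = r, n = n)$bf10
      bm <- bf_correlation(r = -r, n = n)$bf10
      expect_equal(bp, bm, tolerance = 1e-8)
      expect_gt(bp, prev)
      prev <- bp
    }
  }
  # the two one-sided factors average to the two-sided one
  two <- bf_correlation(r = 0.592, n = 20)$bf10
  up <- bf_correlation(r = 0.592, n = 20, alternative = "greater")$bf10
  dn <- bf_correlation(r = 0.592, n = 20, alternative = "less")$bf10
  expect_equal((up + dn) / 2, two, tolerance = 1e-8)
})

test_that("the ANOVA integrator matches its oracle and the t test", {
  set.seed(33)
  g3 <- list(rnorm(12, 0), rnorm(15, 0.7), rnorm(10, -0.3))
  res <- bf_anova_oneway(g3)
  expect_equal(res$bf10, oracle_bf_anova(g3), tolerance = 1e-6)

  a <- rnorm(20); b <- rnorm(20, 0.8)
  # two balanced groups: equivalent to the JZS t test at width sqrt(2)*0.5
  expect_equal(bf_anova_oneway(list(a, b))$bf10,
               bf_ttest_independent(x = a, y = b)$bf10,
               tolerance = 0.05)

  ident <- list(rep(1, 10), rep(1, 12), rep(1, 9))
  expect_lt(bf_anova_oneway(ident)$bf10, 1)
  # zero within-group variance with distinct means: perfect separation
  expect_warning(sep <- bf_anova_oneway(list(rep(0, 5), rep(1, 5))),
                 "infinite")
  expect_true(sep$bf10 > 1)
  expect_error(bf_anova_oneway(list(rnorm(5))), "two groups")
})

test_that("contingency Bayes factors match the direct-integral oracle", {
  tab <- matrix(c(24, 35, 12, 11), 2)
  expect_equal(bf_contingency(tab)$bf10, oracle_bf_contingency_2x2(tab),
               tolerance = 1e-8)
  tab2 <- matrix(c(5, 30, 25, 10), 2)
  expect_equal(bf_contingency(tab2)$bf10, oracle_bf_contingency_2x2(tab2),
               tolerance = 1e-8)
  expect_equal(bf_contingency(tab2, concentration = 2)$bf10,
               oracle_bf_contingency_2x2(tab2, 2), tolerance = 1e-8)
  # proportional rows carry no evidence for association
  expect_lt(bf_contingency(matrix(c(10, 20, 20, 40), 2))$bf10, 1)
  expect_error(bf_contingency(matrix(c(0, 5, 0, 7), 2, byrow = TRUE)),
               "margin")
  expect_error(bf_contingency(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("posterior credible intervals for delta have ~95% null coverage", {
  set.seed(34)
  n_sim <- 500
  n <- 25
  covered <- vapply(seq_len(n_sim), function(i) {
    d <- rnorm(n, 0, 1)
    res <- bf_ttest_paired(x = d)
    res$ci95[1] <= 0 && res$ci95[2] >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("every result records its prior and sample sizes", {
  res <- bf_ttest_independent(m1 = 1, sd1 = 1, n1 = 10, m2 = 0, sd2 = 1,
                              n2 = 12)
  expect_equal(res$prior$cauchy_width, sqrt(2) / 2)
  expect_equal(unlist(res$n_info), c(n1 = 10, n2 = 12))
  expect_lt(res$ci95[1], res$ci95[2])
  resc <- bf_correlation(r = 0.3, n = 30, beta_width = 2)
  expect_equal(resc$prior$beta_width, 2)
})
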