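test_that("routing follows the gated decision tree exactly", {
  set.seed(2)
  norm3 <- lapply(1:3, function(i) rnorm(12))
  skew3 <- lapply(1:3, function(i) exp(rnorm(30, 0, 1.5)))
  norm2 <- lapply(1:2, function(i) rnorm(12))
  skew2 <- lapply(1:2, function(i) exp(rnorm(30, 0, 1.5)))

  r <- compare_groups(norm3)
  expect_equal(r$test_name, "one-way ANOVA")
  expect_false(is.null(r$posthoc))
  r <- compare_groups(skew3)
  expect_equal(r$test_name, "Kruskal-Wallis")
  expect_equal(nrow(r$posthoc), 3L)
  r <- compare_groups(norm2)
  expect_equal(r$test_name, "t-test")
  expect_null(r$posthoc)
  r <- compare_groups(skew2)
  expect_equal(r$test_name, "Mann-Whitney U")
  expect_error(compare_groups(list(rnorm(5))), ">= 2")
})

test_that("adjusted post hoc p-values dominate raw ones and stay in [0, 1]", {
  set.seed(6)
  for (i in 1:10) {
    gr <- lapply(1:4, function(j) rnorm(8, j * runif(1)))
    r <- compare_groups(gr)
    if (!is.null(r$posthoc)) {
      expect_true(all(r$posthoc$p_adj >= r$posthoc$p_raw - 1e-12))
      expect_true(all(r$posthoc$p_adj <= 1))
      expect_true(all(r$posthoc$p_raw >= 0 & r$posthoc$p_raw <= 1))
    }
    expect_gte(r$p_value, 0)
    expect_lte(r$p_value, 1)
  }
})

test_that("Dunn contrasts agree with direct rank-sum arithmetic", {
  # tiny case computed from first principles: ranks of pooled data
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  ph <- cochleaquant:::dunn_posthoc(g, names(g))
  N <- 9
  se <- sqrt(N * (N + 1) / 12 * (1 / 3 + 1 / 3))
  z_ab <- (mean(1:3) - mean(4:6)) / se
  expect_equal(ph$statistic[ph$contrast == "a vs b"], z_ab)
  expect_equal(ph$p_raw[ph$contrast == "a vs b"],
               2 * pnorm(-abs(z_ab)))
})

test_that("normality gate behaves as a 5% test under normal residuals", {
  passes <- vapply(1:200, function(s) {
    set.seed(s)
    gr <- list(rnorm(70, 5), rnorm(70, 8), rnorm(60, 2))
    residual_normality(gr)$normal
  }, logical(1))
  expect_gt(mean(passes), 0.90)
  expect_lt(mean(passes), 0.99)

  fails <- vapply(1:100, function(s) {
    set.seed(s)
    gr <- list(runif(70)^3, runif(70)^3, runif(60)^3)
    !residual_normality(gr)$normal
  }, logical(1))
  expect_gt(mean(fails), 0.99)
})

test_that("degenerate groups force the nonparametric branch with a warning", {
  expect_warning(g1 <- residual_normality(list(c(1, 2), c(1, 2, 3))), "n < 3")
  expect_false(g1$normal)
  expect_warning(g2 <- residual_normality(list(rep(4, 5), rep(4, 6))),
                 "zero residual variance")
  expect_false(g2$normal)
})

test_that("percent change arithmetic and null behaviour", {
  expect_equal(percent_change(rep(16, 4), rep(10.4, 4)), 35)
  x <- rnorm(10, 7)
  expect_equal(percent_change(x, x), 0)
  expect_error(percent_change(c(-1, 1), 5), "zero")
})

test_that("percent change is unbiased on planted cohort effects", {
  est <- vapply(1:200, function(s) {
    set.seed(s)
    percent_change(rnorm(12, 16, 2.5), rnorm(12, 16 * 0.7, 2.5))
  }, numeric(1))
  expect_lt(abs(mean(est) - 30), 2)
})

test_that("cohort simulation: determinism, labels, planted effect size", {
  des <- cohort_design(arms = c("control", "exposed"), seed = 42)
  a <- simulate_cohort(des)
  b <- simulate_cohort(des)
  expect_identical(a, b)
  expect_true(all(a$genotype %in% c("WT", "a9KO", "a9KI")))
  expect_error(cohort_design(genotypes = "B6"), "genotype")
  expect_error(cohort_design(n_per_group = 0), "n_per_group")

  syn <- a[a$metric == "synapses_per_ihc" & a$genotype == "WT", ]
  pc <- percent_change(syn$value[syn$arm == "control"],
                       syn$value[syn$arm == "exposed"])
  expect_equal(pc, 100 * (16 - 10.5) / 16, tolerance = 12)
})

test_that("summarize_cohort runs planned comparisons and reports censoring", {
  des <- cohort_design(arms = c("control", "exposed"),
                       effects = rbind(default_cohort_effects(),
                                       data.frame(metric = "abr_threshold_db",
                                                  genotype = "a9KO",
                                                  arm = "exposed",
                                                  mean = 75, sd = 6)),
                       seed = 7)
  tb <- simulate_cohort(des)
  plan <- list(
    list(metric = "synapses_per_ihc", factor = "genotype",
         filter = list(arm = "control")),
    list(metric = "abr_threshold_db", factor = "arm",
         filter = list(genotype = "a9KO")))
  rep <- summarize_cohort(tb, plan)
  expect_equal(nrow(rep$results), 2L)
  expect_gt(rep$results$n_censored_excluded[2], 0)
  expect_true(all(c("mean", "sem", "median", "iqr_lo", "iqr_hi") %in%
                    names(rep$descriptives)))
  # empty plan -> descriptives only
  rep0 <- summarize_cohort(tb)
  expect_equal(nrow(rep0$results), 0L)
  expect_gt(nrow(rep0$descriptives), 0L)
  expect_error(summarize_cohort(tb, list(list(metric = "nope",
                                              factor = "genotype"))),
               "absent metric 'nope'")
})

test_that("identical inputs give identical routing and p-values", {
  set.seed(9)
  gr <- lapply(1:3, function(i) rnorm(10))
  r1 <- compare_groups(gr)
  r2 <- compare_groups(gr)
  expect_identical(r1[c("test_name", "p_value", "statistic")],
                   r2[c("test_name", "p_value", "statistic")])
})
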