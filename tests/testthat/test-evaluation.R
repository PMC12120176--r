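test_that("auROC handles separation, null labels, and matches the all-pairs oracle", {
  expect_equal(compute_auroc(c(5, 6, 7, 1, 2, 3),
                             c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auroc, 1)
  set.seed(101)
  null <- compute_auroc(stats::rnorm(4000), rep(c(TRUE, FALSE), 2000))
  expect_lt(abs(null$auroc - 0.5), 0.03)
  # all-pairs Mann-Whitney oracle, with ties, on 25 random small inputs
  for (r in 1:25) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(compute_auroc(scores, labels)$auroc,
                 auroc_pairs_oracle(scores, labels), tolerance = 1e-12)
  }
  expect_error(compute_auroc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("auROC is antisymmetric under score negation and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(303)
  scores <- stats::rnorm(150)  # tie-free
  labels <- stats::rbinom(150, 1, 0.4) == 1
  a <- compute_auroc(scores, labels)$auroc
  b <- compute_auroc(-scores, labels)$auroc
  expect_equal(a + b, 1, tolerance = 1e-12)
  proc_auc <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                             direction = "<")))
  expect_equal(a, proc_auc, tolerance = 1e-12)
})

test_that("bootstrap auROC comparison: identity, symmetry, and power", {
  cohort <- sim_cohort(seed = 51, n = 400)
  lab <- cohort$functional_class == "LOF"
  same <- bootstrap_auroc_test(cohort$AM, cohort$AM, lab, n_boot = 200,
                               seed = 1)
  expect_equal(same$delta_auroc, 0)
  expect_equal(same$p_value, 1)
  ab <- bootstrap_auroc_test(cohort$AM, cohort$DDG_PDB, lab, n_boot = 400,
                             seed = 2)
  ba <- bootstrap_auroc_test(cohort$DDG_PDB, cohort$AM, lab, n_boot = 400,
                             seed = 2)
  expect_equal(ab$delta_auroc, -ba$delta_auroc)
  expect_equal(ab$p_value, ba$p_value)
  # informative vs pure-noise score separates decisively
  set.seed(61)
  for (s in 1:3) {
    n <- 1000
    lab2 <- rep(c(TRUE, FALSE), c(220, 780))
    good <- stats::rnorm(n, mean = ifelse(lab2, 1.5, 0))
    noise <- stats::rnorm(n)
    res <- bootstrap_auroc_test(good, noise, lab2, n_boot = 400, seed = s)
    expect_lt(res$p_value, 0.01)
  }
  expect_warning(bootstrap_auroc_test(cohort$AM, cohort$BD, lab, n_boot = 50,
                                      seed = 1), "n_boot")
})

test_that("pearson correlation matches the direct formula and rejects degenerate input", {
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  set.seed(71)
  for (r in 1:10) {
    n <- sample(3:100, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_r(x, y), oracle, tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(c(1, NA, 3), 1:3), "non-finite")
})

test_that("rank-sum test: exact enumeration for small samples, approximation for large", {
  # all 20 assignments of ranks {1..6} to two groups of 3: one-sided tail
  # 1/20, two-sided p = 0.1
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(81)
  big <- rank_sum_test(stats::rnorm(300), stats::rnorm(300, mean = 2))
  expect_lt(big$p, 1e-6)
})

test_that("diagnostic metrics recover hand-computable tables and scale invariance", {
  sym <- diagnostic_metrics(5, 5, 5, 5)
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    expect_equal(sym[[m]]$estimate, 50)
  }
  expect_error(diagnostic_metrics(0, 0, 0, 10), "sensitivity")
  expect_error(diagnostic_metrics(5, 5, 0, 0), "specificity")
  # percent point estimates are invariant under scaling all four cells
  a <- diagnostic_metrics(28, 5, 14, 104)
  b <- diagnostic_metrics(28 * 7, 5 * 7, 14 * 7, 104 * 7)
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    expect_equal(a[[m]]$estimate, b[[m]]$estimate, tolerance = 1e-12)
    expect_true(all(a[[m]]$ci >= 0 & a[[m]]$ci <= 100))
  }
  # Clopper-Pearson bounds come from the exact binomial test
  cp <- as.numeric(stats::binom.test(28, 33)$conf.int) * 100
  expect_equal(a$sensitivity$ci, cp, tolerance = 1e-10)
})
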