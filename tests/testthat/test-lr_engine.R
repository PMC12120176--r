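test_that("zone counts match a hand count on the toy cohort", {
  counts <- count_zones(toy_cohort(), three_zone("AM", 0.65, 0.75))
  expect_equal(counts$lof_path, 2L)
  expect_equal(counts$lof_gray, 0L)
  expect_equal(counts$lof_benign, 1L)
  expect_equal(counts$func_path, 1L)
  expect_equal(counts$func_gray, 0L)
  expect_equal(counts$func_benign, 2L)  # 0.6 falls at or below the benign cut
  expect_equal(counts$n_lof, 3L)
  expect_equal(counts$n_func, 3L)
})

test_that("coincident thresholds give an empty gray zone", {
  cohort <- sim_cohort(seed = 5, n = 400)
  med <- stats::median(cohort$AM)
  counts <- count_zones(cohort, three_zone("AM", med, med))
  expect_equal(counts$lof_gray + counts$func_gray, 0L)
  expect_equal(counts$gray_fraction, 0)
})

test_that("equal zone proportions give LR = 1 and lower-is-pathogenic mirrors", {
  zc <- zone_counts(0, 90, 10, 0, 900, 100)
  est <- lr_pathogenic(zc)
  expect_equal(est$lr, 1)
  expect_equal(est$log2_lr, 0)
  # mirrored direction: low stability scores pathogenic
  cohort <- toy_cohort()
  cohort$NEG <- -cohort$AM
  mirrored <- count_zones(cohort,
                          three_zone("NEG", -0.65, -0.75,
                                     direction = "LOWER_IS_PATHOGENIC"))
  original <- count_zones(cohort, three_zone("AM", 0.65, 0.75))
  expect_equal(mirrored$lof_path, original$lof_path)
  expect_equal(mirrored$func_benign, original$func_benign)
})

test_that("zone LRs satisfy the normalisation identity and invert under label swap", {
  cohort <- sim_cohort(seed = 9, n = 1000)
  for (tool in c("AM", "DDG_AF", "BD")) {
    z <- three_zone(tool, stats::quantile(cohort[[tool]], 0.3),
                    stats::quantile(cohort[[tool]], 0.7))
    ct <- count_zones(cohort, z)
    p_lof <- c(ct$lof_benign, ct$lof_gray, ct$lof_path) / ct$n_lof
    p_func <- c(ct$func_benign, ct$func_gray, ct$func_path) / ct$n_func
    expect_equal(sum(p_lof), 1, tolerance = 1e-12)
    # sum over zones of LR_z * P(z | FUNC) telescopes to sum P(z | LoF) = 1
    expect_true(all(p_func > 0))
    expect_equal(sum((p_lof / p_func) * p_func), 1, tolerance = 1e-12)
    # swapping LOF and FUNC labels inverts every LR exactly
    swapped <- cohort
    swapped$functional_class <- ifelse(cohort$functional_class == "LOF",
                                       "FUNC", "LOF")
    ct_sw <- count_zones(swapped, z)
    expect_equal(lr_pathogenic(ct_sw)$lr, 1 / lr_pathogenic(ct)$lr,
                 tolerance = 1e-12)
    expect_equal(lr_benign(ct_sw)$lr, 1 / lr_benign(ct)$lr, tolerance = 1e-12)
  }
})

test_that("LR equals sensitivity/(1-specificity) when the gray zone is empty", {
  cohort <- sim_cohort(seed = 13, n = 600)
  cut <- stats::median(cohort$AM)
  ct <- count_zones(cohort, three_zone("AM", cut, cut))
  sens <- ct$lof_path / ct$n_lof
  spec <- ct$func_benign / ct$n_func
  expect_equal(lr_pathogenic(ct)$lr, sens / (1 - spec), tolerance = 1e-12)
})

test_that("widening the gray zone never decreases the gray fraction", {
  cohort <- sim_cohort(seed = 21, n = 500)
  cuts <- stats::quantile(cohort$AM, c(0.2, 0.35, 0.5, 0.65, 0.8))
  prev <- -1
  for (k in 0:2) {
    ct <- count_zones(cohort, three_zone("AM", cuts[3 - k], cuts[3 + k]))
    expect_gte(ct$gray_fraction, prev)
    prev <- ct$gray_fraction
  }
})

test_that("confidence interval behaviour: degenerate proportions, nesting, correction flag", {
  # both proportions 1: zero-width interval at log2 LR = 0
  ci <- log2_lr_ci(50, 50, 70, 70)
  expect_equal(as.numeric(ci), c(0, 0))
  # higher level strictly contains lower level
  ci95 <- log2_lr_ci(20, 100, 30, 200, level = 0.95)
  ci99 <- log2_lr_ci(20, 100, 30, 200, level = 0.99)
  expect_lt(ci99[1], ci95[1])
  expect_gt(ci99[2], ci95[2])
  # zero numerator: Haldane-Anscombe correction, flagged
  ci0 <- log2_lr_ci(0, 50, 10, 100)
  expect_true(attr(ci0, "corrected"))
  expect_true(all(is.finite(ci0)))
  est <- lr_estimate(0, 50, 10, 100)
  expect_true(est$corrected)
  expect_gt(est$lr, 0)
})

test_that("strength mapping snaps to the 1/2/4/8 point scale with a null band", {
  mk <- function(log2lr, ci = log2lr + c(-0.2, 0.2)) {
    structure(list(lr = 2^log2lr, log2_lr = log2lr, ci95_log2 = ci,
                   x1 = 1, n1 = 2, x2 = 1, n2 = 2, corrected = FALSE),
              class = "lr_estimate")
  }
  expect_equal(map_strength(mk(2.810))$strength, "MODERATE")
  expect_equal(map_strength(mk(2.810))$direction, "PATHOGENIC")
  expect_equal(map_strength(mk(0.4))$strength, "NONE")
  s <- map_strength(mk(-4.603))
  expect_equal(s$strength, "STRONG")
  expect_equal(s$direction, "BENIGN")
  expect_equal(s$points, -4L)
  # ties snap to the lower tier
  expect_equal(map_strength(mk(1.5))$points, 1L)
  expect_equal(map_strength(mk(3.0))$points, 2L)
  expect_equal(map_strength(mk(6.0))$points, 4L)
  expect_equal(map_strength(mk(9.0))$points, 8L)
  # CI through 0 demotes to no evidence when required
  est <- mk(1.2, ci = c(-0.1, 2.5))
  expect_equal(map_strength(est, require_ci_excludes_null = TRUE)$strength,
               "NONE")
  expect_equal(map_strength(est)$strength, "SUPPORTING")
})

test_that("threshold search agrees with a brute-force sweep and honours constraints", {
  cohort <- sim_cohort(seed = 31, n = 700)
  grid <- seq(0.05, 0.95, by = 0.09)
  front <- search_thresholds(cohort, "AM", grid,
                             min_abs_log2_each_side = 1,
                             max_gray_fraction = 0.3)
  expect_gt(nrow(front), 0)
  # oracle: independent brute-force sweep over the same grid
  best_gray_at_moderate <- Inf
  for (b in grid) for (p in grid[grid >= b]) {
    ev <- tryCatch(evaluate_tool(cohort, three_zone("AM", b, p),
                                 require_ci_excludes_null = TRUE),
                   error = function(e) NULL)
    if (is.null(ev)) next
    if (ev$strength_path$points >= 2 && ev$strength_benign$points <= -2 &&
        abs(ev$lr_path$log2_lr) >= 1 && abs(ev$lr_benign$log2_lr) >= 1 &&
        ev$gray_fraction <= 0.3) {
      best_gray_at_moderate <- min(best_gray_at_moderate, ev$gray_fraction)
    }
  }
  # the front contains a pair achieving Moderate both sides at the minimal
  # gray fraction found by the sweep
  mod <- front[front$points_path >= 2 & front$points_benign <= -2, ]
  expect_gt(nrow(mod), 0)
  expect_equal(min(mod$gray_fraction), best_gray_at_moderate, tolerance = 1e-12)
  # every front member is feasible and not dominated by any other member
  for (i in seq_len(nrow(front))) {
    dominated <- any(front$min_abs_log2 > front$min_abs_log2[i] &
                       front$gray_fraction < front$gray_fraction[i])
    expect_false(dominated)
  }
  # unattainable strength requirement yields an empty, diagnosed result
  none <- search_thresholds(cohort, "AM", grid,
                            min_abs_log2_each_side = Inf)
  expect_equal(nrow(none), 0)
  expect_match(attr(none, "diagnostics"), "no threshold pair")
  expect_error(search_thresholds(cohort, "AM", numeric(0)), "empty")
})

test_that("perfectly separated classes admit a zero-gray pair with corrected extreme LRs", {
  n <- 40
  cohort <- score_table(paste0("s", 1:n),
                        mave_score = rep(c(-2, 0), each = n / 2),
                        functional_class = rep(c("LOF", "FUNC"), each = n / 2),
                        scores = list(AM = c(stats::runif(n / 2, 0.8, 1),
                                             stats::runif(n / 2, 0, 0.2))))
  front <- search_thresholds(cohort, "AM", c(0.3, 0.5, 0.7),
                             min_abs_log2_each_side = 1,
                             max_gray_fraction = 1)
  expect_true(any(front$gray_fraction == 0))
  ct <- count_zones(cohort, three_zone("AM", 0.5, 0.5))
  est <- lr_pathogenic(ct)
  expect_true(est$corrected)
  expect_equal(est$lr, ((n / 2 + 0.5) / (n / 2 + 1)) / (0.5 / (n / 2 + 1)))
})
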