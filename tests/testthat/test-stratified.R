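test_that("a single all-inclusive stratum reproduces the unstratified evaluation", {
  cohort <- sim_cohort(seed = 17, n = 500)
  zone <- three_zone("AM", 0.65, 0.75)
  whole <- list(stratum("ALL", function(tb) rep(TRUE, nrow(tb))))
  per <- stratified_evaluate(cohort, whole, zone)
  ev <- evaluate_tool(cohort, zone)
  expect_equal(per$ALL$lr_path$lr, ev$lr_path$lr)
  expect_equal(per$ALL$lr_benign$lr, ev$lr_benign$lr)
  expect_equal(per$ALL$gray_fraction, ev$gray_fraction)
})

test_that("non-partitioning strata are rejected; RSA strata partition and collapse exactly", {
  cohort <- sim_cohort(seed = 19, n = 600)
  overlap <- list(stratum("A", function(tb) tb$rsa < 50),
                  stratum("B", function(tb) tb$rsa < 80))
  expect_error(stratified_evaluate(cohort, overlap, three_zone("AM", 0.65, 0.75)),
               "partition")
  per <- stratified_evaluate(cohort, rsa_strata(), three_zone("AM", 0.65, 0.75))
  # weighted-count identity: per-stratum zone counts sum to the pooled counts
  pooled <- count_zones(cohort, three_zone("AM", 0.65, 0.75))
  get <- function(f) sum(vapply(per, function(ev) {
    if (isTRUE(ev$underpowered)) 0L else ev$counts[[f]]
  }, numeric(1)))
  for (f in c("lof_path", "lof_benign", "func_path", "func_benign",
              "n_lof", "n_func")) {
    expect_equal(get(f), pooled[[f]])
  }
})

test_that("benignity evidence at exposed residues is weaker than at buried residues", {
  # the generator puts only 7% impaired variants at exposed residues, and
  # class-conditional stability distributions overlap; the buried stratum
  # should show clearly stronger (more negative, significant) benignity LRs
  # than the exposed stratum on average
  reps <- 25
  sig_buried <- sig_exposed <- logical(reps)
  for (r in seq_len(reps)) {
    cohort <- sim_cohort(seed = 100 + r, n = 800)
    per <- stratified_evaluate(cohort, rsa_strata(),
                               three_zone("DDG_AF", 1.5, 2.5))
    sig_buried[r] <- !isTRUE(per$BURIED$underpowered) &&
      per$BURIED$significant_benign
    sig_exposed[r] <- !isTRUE(per$EXPOSED$underpowered) &&
      per$EXPOSED$significant_benign
  }
  expect_gt(mean(sig_buried), mean(sig_exposed))
  expect_gt(mean(sig_buried), 0.9)
})

test_that("concordance categories behave at the correlation limits", {
  cohort <- sim_cohort(seed = 23, n = 500)
  za <- three_zone("AM", 0.65, 0.75)
  # a perfectly correlated second tool: uninformative category equals the
  # union of the single-tool gray zones (here: identical zones)
  cohort$AM2 <- cohort$AM
  cc <- concordance_evaluate(cohort, za, three_zone("AM2", 0.65, 0.75))
  single <- count_zones(cohort, za)
  expect_equal(cc$uninformative_fraction, single$gray_fraction)
  # anti-correlated tools with symmetric zones: agreement in either
  # direction is impossible, so everything is uninformative
  cohort$ANTI <- 1 - cohort$AM
  cc2 <- concordance_evaluate(cohort, three_zone("AM", 0.1, 0.9),
                              three_zone("ANTI", 0.1, 0.9))
  expect_equal(cc2$uninformative_fraction, 1)
  expect_true(cc2$lr_path$corrected)
})

test_that("independent random tools on a null cohort give concordant LRs near 1", {
  set.seed(77)
  reps <- 40
  log2s <- numeric(0)
  for (r in seq_len(reps)) {
    n <- 400
    tb <- score_table(paste0("n", 1:n),
                      mave_score = rep(c(-2, 0), each = n / 2),
                      functional_class = rep(c("LOF", "FUNC"), each = n / 2),
                      scores = list(T1 = stats::runif(n), T2 = stats::runif(n)))
    cc <- concordance_evaluate(tb, three_zone("T1", 0.4, 0.6),
                               three_zone("T2", 0.4, 0.6))
    log2s <- c(log2s, cc$lr_path$log2_lr, cc$lr_benign$log2_lr)
  }
  # labels are independent of both tools, so concordant LRs centre on 1
  expect_lt(abs(mean(log2s)), 3 * stats::sd(log2s) / sqrt(length(log2s)) + 0.1)
})

test_that("cascade assignment partitions the cohort and demotes null leaves", {
  cohort <- sim_cohort(seed = 29, n = 1000)
  res <- cascade_assign(cohort, default_cascade())
  expect_equal(nrow(res$assignments), nrow(cohort))
  expect_true(all(table(res$assignments$leaf) > 0))
  # demotion to GRAY is idempotent: re-deriving emitted labels changes nothing
  emitted_again <- ifelse(res$assignments$emitted == "GRAY", "GRAY",
                          res$assignments$emitted)
  expect_identical(emitted_again, res$assignments$emitted)
  # every demoted leaf has a CI spanning 0
  for (lf in names(res$leaf_lr)) {
    e <- res$leaf_lr[[lf]]
    if (e$demoted) {
      ci <- e$estimate$ci95_log2
      expect_true((ci[1] <= 0 && ci[2] >= 0) || abs(e$estimate$log2_lr) < 0.5)
    }
  }
})

test_that("cascade leaf LRs are monotone from concordant-pathogenic to concordant-benign", {
  cohort <- sim_cohort(seed = 37, n = 1500)
  res <- cascade_assign(cohort, default_cascade())
  l2 <- function(lf) res$leaf_lr[[lf]]$estimate$log2_lr
  expect_gt(l2("CORE_PATH_CONCORDANT"), l2("CORE_PATH"))
  expect_gt(l2("CORE_PATH"), l2("CORE_BENIGN"))
  expect_gt(l2("CORE_BENIGN"), l2("CORE_BENIGN_CONCORDANT"))
})

test_that("a depth-1 cascade on one tool reduces to the single-tool zones", {
  cohort <- sim_cohort(seed = 41, n = 600)
  tree <- cascade_node("AM", "ge", 0.75, yes = "PATH",
                       no = cascade_node("AM", "le", 0.65,
                                         yes = "BENIGN", no = "GRAY"))
  res <- cascade_assign(cohort, tree)
  ct <- count_zones(cohort, three_zone("AM", 0.65, 0.75))
  cls <- cohort$functional_class
  lf <- res$assignments$leaf
  expect_equal(sum(lf == "PATH" & cls == "LOF"), ct$lof_path)
  expect_equal(sum(lf == "BENIGN" & cls == "FUNC"), ct$func_benign)
  expect_equal(res$leaf_lr$PATH$estimate$lr, lr_pathogenic(ct)$lr)
})

test_that("variants missing a cascade field are assigned GRAY and counted", {
  cohort <- sim_cohort(seed = 43, n = 200)
  cohort$DDG_AF[1:5] <- NA
  # route the first variants into the stability-score nodes
  cohort$rsa[1:5] <- 10
  cohort$AM[1:5] <- 0.9
  res <- cascade_assign(cohort, default_cascade())
  expect_equal(res$n_missing_field, 5L)
  expect_true(all(res$assignments$emitted[1:5] == "GRAY"))
})
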