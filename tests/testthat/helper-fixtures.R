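# Shared fixtures, built in code.

# Tiny fully-specified LoF/FUNC cohort with hand-computable zone counts:
# 3 LoF variants scoring 0.9 / 0.8 / 0.5 and 3 FUNC scoring 0.1 / 0.6 / 0.9.
toy_cohort <- function() {
  score_table(variant_id = paste0("v", 1:6),
              domain = "RING",
              mave_score = c(-2, -2, -2, 0, 0, 0),
              rsa = c(10, 20, 40, 50, 70, 80),
              functional_class = rep(c("LOF", "FUNC"), each = 3),
              scores = list(AM = c(0.9, 0.8, 0.5, 0.1, 0.6, 0.9)))
}

# Medium synthetic LoF/FUNC cohort for property tests.
sim_cohort <- function(seed = 11, n = 800) {
  cfg <- default_generator_config(n_variants = n, seed = seed)
  build_analysis_cohort(classify_variants(generate_mave_cohort(cfg)))
}

# All-pairs Mann-Whitney oracle for the auROC (ties count half).
auroc_pairs_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Full hypergeometric enumeration oracle for the two-sided Fisher test.
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Write a score_table out as a plain TSV (full precision) for IO tests.
write_cohort_tsv <- function(tb, path) {
  write_results_table(as.data.frame(tb), path)
  path
}
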