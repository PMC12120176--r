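# Discrimination and association metrics: auROC (rank-based), paired
# bootstrap auROC comparison, correlation, rank-sum test, and diagnostic
# test evaluation with the CI conventions of standard clinical calculators.

#' ROC curve and area under it
#'
#' The area is computed from the Mann-Whitney U statistic via average ranks,
#' so ties count one half; it equals the probability that a random positive
#' (LoF) scores above a random negative (FUNC).
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1 vector; `TRUE`/1 marks the positive (LoF)
#'   class.
#' @param higher_is_positive set `FALSE` for tools where lower scores mark
#'   the positive class.
#' @return a `roc_curve` list: `thresholds`, `tpr`, `fpr` (curve traced from
#'   the most stringent threshold down) and `auroc`.
#' @export
compute_auroc <- function(scores, labels, higher_is_positive = TRUE) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  if (!higher_is_positive) scores <- -scores
  r <- rank(scores)  # average ranks: ties count half in U
  auroc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  structure(list(thresholds = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr),
                 auroc = auroc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' Paired bootstrap comparison of two auROCs
#'
#' Both tools are scored on the same variants; the cohort is resampled with
#' replacement separately within the positive and negative classes
#' (stratified, preserving prevalence), the auROC difference recomputed per
#' resample, and a two-sided p-value taken from the normalised observed
#' difference `D = delta / sd(bootstrap deltas)` against a standard normal.
#'
#' @param scores_a,scores_b paired numeric score vectors.
#' @param labels positive-class indicator, as in [compute_auroc].
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param seed integer seed for reproducibility.
#' @return list with `delta_auroc` (a minus b), `p_value`, `auroc_a`,
#'   `auroc_b`, `n_boot`.
#' @export
bootstrap_auroc_test <- function(scores_a, scores_b, labels, n_boot = 10000,
                                 seed = NULL) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  if (n_boot < 100) warning("n_boot < 100 gives an unstable p-value")
  labels <- as.logical(labels)
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  scores_a <- scores_a[keep]; scores_b <- scores_b[keep]
  labels <- labels[keep]
  if (!is.null(seed)) set.seed(seed)
  auc_a <- compute_auroc(scores_a, labels)$auroc
  auc_b <- compute_auroc(scores_b, labels)$auroc
  delta <- auc_a - auc_b
  pos <- which(labels); neg <- which(!labels)
  deltas <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    lb <- labels[idx]
    compute_auroc(scores_a[idx], lb)$auroc -
      compute_auroc(scores_b[idx], lb)$auroc
  }, numeric(1))
  s <- stats::sd(deltas)
  p <- if (s == 0) 1 else 2 * stats::pnorm(-abs(delta / s))
  list(delta_auroc = delta, p_value = min(p, 1), auroc_a = auc_a,
       auroc_b = auc_b, n_boot = n_boot)
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length finite numeric vectors (n >= 3).
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  stats::cor(x, y, method = "pearson")
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when both samples have at most 10 observations and no
#' ties; the normal approximation with tie correction otherwise.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (Mann-Whitney W) and `p`.
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  exact <- length(x) <= 10 && length(y) <= 10 && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

invlogit <- function(x) 1 / (1 + exp(-x))

#' Diagnostic test evaluation from a 2x2 confusion table
#'
#' Point estimates as percents; sensitivity, specificity and accuracy get
#' Clopper-Pearson exact binomial intervals, PPV and NPV get
#' prevalence-form logit intervals (the Mercaldo construction used by
#' standard online diagnostic calculators):
#' `var(logit PPV) = (1-se)/(n1*se) + sp/(n0*(1-sp))` and
#' `var(logit NPV) = se/(n1*(1-se)) + (1-sp)/(n0*sp)`, where `n1 = tp+fn`
#' and `n0 = fp+tn`.
#'
#' @param tp,fn,fp,tn non-negative integer cell counts; positives are the
#'   LoF (pathogenicity proxy) class.
#' @param level confidence level.
#' @return a `diagnostic_metrics` list of `estimate` (percent) and `ci`
#'   (percent bounds) per metric, plus the cell counts.
#' @export
diagnostic_metrics <- function(tp, fn, fp, tn, level = 0.95) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  stopifnot(all(cells >= 0), sum(cells) > 0)
  if (tp + fn == 0) stop("sensitivity undefined: no positive-class observations")
  if (fp + tn == 0) stop("specificity undefined: no negative-class observations")
  if (tp + fp == 0) stop("PPV undefined: no positive calls")
  if (tn + fn == 0) stop("NPV undefined: no negative calls")
  n1 <- tp + fn; n0 <- fp + tn; total <- n1 + n0
  se <- tp / n1; sp <- tn / n0
  cp <- function(x, n) as.numeric(stats::binom.test(x, n,
                                                    conf.level = level)$conf.int)
  z <- stats::qnorm(1 - (1 - level) / 2)
  logit_ci <- function(p, v) {
    if (p == 0 || p == 1) return(c(p, p))  # degenerate; exact bound
    invlogit(stats::qlogis(p) + c(-1, 1) * z * sqrt(v))
  }
  ppv <- tp / (tp + fp); npv <- tn / (tn + fn)
  v_ppv <- if (tp > 0 && fp > 0) (1 - se) / (n1 * se) + sp / (n0 * (1 - sp)) else NA
  v_npv <- if (tn > 0 && fn > 0) se / (n1 * (1 - se)) + (1 - sp) / (n0 * sp) else NA
  metric <- function(est, ci) list(estimate = 100 * est,
                                   ci = 100 * c(max(ci[1], 0), min(ci[2], 1)))
  structure(list(
    sensitivity = metric(se, cp(tp, n1)),
    specificity = metric(sp, cp(tn, n0)),
    ppv = metric(ppv, if (is.na(v_ppv[1])) c(ppv, ppv) else logit_ci(ppv, v_ppv)),
    npv = metric(npv, if (is.na(v_npv[1])) c(npv, npv) else logit_ci(npv, v_npv)),
    accuracy = metric((tp + tn) / total, cp(tp + tn, total)),
    tp = tp, fn = fn, fp = fp, tn = tn),
    class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    cat(sprintf("%-12s %5.1f%% (%.1f-%.1f)\n", m, x[[m]]$estimate,
                x[[m]]$ci[1], x[[m]]$ci[2]))
  }
  invisible(x)
}
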