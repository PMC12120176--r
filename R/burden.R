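# Case-control burden association from carrier counts per score stratum:
# carrier-vs-noncarrier odds ratios with Woolf confidence intervals and
# two-sided Fisher exact p-values.

#' Carrier counts for one score stratum
#'
#' @param stratum stratum label (e.g. a score interval).
#' @param carriers_cases,carriers_controls carriers of any qualifying variant.
#' @param total_cases,total_controls cohort sizes.
#' @param n_variants number of unique qualifying variants (descriptive).
#' @return a `carrier_counts` list.
#' @export
carrier_counts <- function(stratum, carriers_cases, carriers_controls,
                           total_cases, total_controls, n_variants = NA_integer_) {
  stopifnot(carriers_cases >= 0, carriers_controls >= 0,
            carriers_cases <= total_cases, carriers_controls <= total_controls)
  structure(list(stratum = stratum, n_variants = n_variants,
                 carriers_cases = carriers_cases,
                 carriers_controls = carriers_controls,
                 total_cases = total_cases, total_controls = total_controls),
            class = "carrier_counts")
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Summation of hypergeometric tables with probability not exceeding that of
#' the observed table (the standard two-sided convention).
#'
#' @param a,b,c,d non-negative cell counts (rows: cases/controls, columns:
#'   carrier/non-carrier).
#' @return p-value in (0, 1\].
#' @export
fisher_exact_p <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0), a + b + c + d > 0)
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                     alternative = "two.sided")$p.value
}

#' Burden odds ratio for one stratum
#'
#' `OR = (a/(N_case - a)) / (c/(N_ctrl - c))` with `a`, `c` the case and
#' control carrier counts; confidence interval by Woolf
#' (`ln OR +/- z*sqrt(1/a + 1/b + 1/c + 1/d)`); p by two-sided Fisher exact.
#' A Haldane correction (0.5 per cell) is applied, and flagged, when any
#' cell is zero.
#'
#' @param counts a [carrier_counts] object.
#' @param level confidence level.
#' @return an `or_estimate` list: `odds_ratio`, `ci95`, `p`, `method`,
#'   `corrected`, `significant` (CI excludes 1).
#' @export
burden_or <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "carrier_counts"))
  a <- counts$carriers_cases
  c_ <- counts$carriers_controls
  b <- counts$total_cases - a
  d <- counts$total_controls - c_
  if (a == 0 && c_ == 0) stop("no carriers in either arm")
  if (b <= 0 || d <= 0) stop("non-carrier count must be positive in both arms")
  p <- fisher_exact_p(a, b, c_, d)
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  or <- (a / b) / (c_ / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * sqrt(1 / a + 1 / b + 1 / c_ + 1 / d))
  structure(list(stratum = counts$stratum, odds_ratio = or, ci95 = ci, p = p,
                 method = "carrier OR, Woolf CI, Fisher exact p",
                 corrected = corrected,
                 significant = ci[1] > 1 || ci[2] < 1),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("%s: OR = %.2f (%.2f-%.2f), p = %.3g%s%s\n",
              x$stratum %||% "", x$odds_ratio, x$ci95[1], x$ci95[2], x$p,
              if (x$significant) " *" else "",
              if (x$corrected) " [Haldane-corrected]" else ""))
  invisible(x)
}

#' Burden odds ratios across disjoint strata
#'
#' @param counts_list list of [carrier_counts] objects (disjoint strata).
#' @param level confidence level.
#' @return data frame with one row per stratum: carrier counts, odds ratio,
#'   Woolf CI bounds, Fisher p, and a significance flag (CI excludes 1).
#' @export
stratify_burden <- function(counts_list, level = 0.95) {
  if (length(counts_list) == 0L) {
    return(data.frame(stratum = character(), n_variants = integer(),
                      carriers_cases = integer(), carriers_controls = integer(),
                      odds_ratio = numeric(), ci_lo = numeric(),
                      ci_hi = numeric(), p = numeric(),
                      significant = logical()))
  }
  do.call(rbind, lapply(counts_list, function(cc) {
    est <- burden_or(cc, level)
    data.frame(stratum = cc$stratum, n_variants = cc$n_variants,
               carriers_cases = cc$carriers_cases,
               carriers_controls = cc$carriers_controls,
               odds_ratio = est$odds_ratio, ci_lo = est$ci95[1],
               ci_hi = est$ci95[2], p = est$p,
               significant = est$significant, stringsAsFactors = FALSE)
  }))
}

#' Read a carrier-count table
#'
#' TSV with columns `stratum`, `n_variants`, `carriers_cases`,
#' `carriers_controls`, `total_cases`, `total_controls`.
#'
#' @param path file path.
#' @return list of [carrier_counts] objects.
#' @export
read_carrier_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("stratum", "carriers_cases", "carriers_controls",
            "total_cases", "total_controls")
  missing_col <- setdiff(need, names(df))
  if (length(missing_col)) {
    stop("missing mandatory column(s): ", paste(missing_col, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    carrier_counts(df$stratum[i], df$carriers_cases[i],
                   df$carriers_controls[i], df$total_cases[i],
                   df$total_controls[i],
                   n_variants = df$n_variants[i] %||% NA_integer_)
  })
}
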