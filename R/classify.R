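# Functional classification and RSA binning.
#
# MAVE functional classes follow fixed score cutoffs: functional (FUNC)
# above -0.748, loss-of-function (LOF) below -1.328, intermediate (INT) in
# between. The published cutoffs are strict inequalities, leaving the exact
# boundary values undefined; scores landing exactly on a cutoff are assigned
# INT, the conservative evidence-free class.

#' Functional class score thresholds
#'
#' @param func_min_exclusive scores strictly above this are functional.
#' @param lof_max_exclusive scores strictly below this are loss-of-function.
#' @return a `functional_thresholds` list.
#' @export
functional_thresholds <- function(func_min_exclusive = -0.748,
                                  lof_max_exclusive = -1.328) {
  stopifnot(is.finite(func_min_exclusive), is.finite(lof_max_exclusive))
  if (!(lof_max_exclusive < func_min_exclusive)) {
    stop("lof_max_exclusive must be < func_min_exclusive")
  }
  structure(list(func_min_exclusive = func_min_exclusive,
                 lof_max_exclusive = lof_max_exclusive),
            class = "functional_thresholds")
}

#' RSA bin boundaries
#'
#' Buried: RSA < `buried_max_exclusive`; partially buried:
#' `buried_max_exclusive` <= RSA <= `partial_max_inclusive`; exposed above.
#' Boundary values 30 and 60 fall in the partially buried bin (closed
#' interval).
#'
#' @param buried_max_exclusive upper RSA bound (exclusive) of the buried bin,
#'   percent.
#' @param partial_max_inclusive upper RSA bound (inclusive) of the partially
#'   buried bin, percent.
#' @return an `rsa_binning` list.
#' @export
rsa_binning <- function(buried_max_exclusive = 30, partial_max_inclusive = 60) {
  if (!(0 < buried_max_exclusive && buried_max_exclusive < partial_max_inclusive)) {
    stop("require 0 < buried_max_exclusive < partial_max_inclusive")
  }
  structure(list(buried_max_exclusive = buried_max_exclusive,
                 partial_max_inclusive = partial_max_inclusive),
            class = "rsa_binning")
}

#' Assign MAVE functional classes from functional scores
#'
#' @param score numeric vector of finite MAVE functional scores.
#' @param thresholds a [functional_thresholds] object.
#' @return character vector in `{"LOF", "INT", "FUNC"}`.
#' @export
assign_functional_class <- function(score, thresholds = functional_thresholds()) {
  if (any(!is.finite(score))) stop("non-finite MAVE score")
  ifelse(score > thresholds$func_min_exclusive, "FUNC",
         ifelse(score < thresholds$lof_max_exclusive, "LOF", "INT"))
}

#' Assign RSA bins
#'
#' @param rsa numeric vector of relative solvent accessibilities (percent,
#'   non-negative; values above 100 permitted).
#' @param binning an [rsa_binning] object.
#' @return character vector in `{"BURIED", "PARTIAL", "EXPOSED"}`.
#' @export
assign_rsa_bin <- function(rsa, binning = rsa_binning()) {
  if (any(is.na(rsa)) || any(rsa < 0)) stop("rsa must be non-missing and >= 0")
  ifelse(rsa < binning$buried_max_exclusive, "BURIED",
         ifelse(rsa <= binning$partial_max_inclusive, "PARTIAL", "EXPOSED"))
}

#' Classify all variants in a score table
#'
#' Fills `functional_class` from `mave_score` and appends an `rsa_bin`
#' column where RSA is available.
#'
#' @param table a `score_table`.
#' @param thresholds a [functional_thresholds] object.
#' @param binning an [rsa_binning] object.
#' @return the table with `functional_class` (and `rsa_bin`) filled in.
#' @export
classify_variants <- function(table, thresholds = functional_thresholds(),
                              binning = rsa_binning()) {
  stopifnot(inherits(table, "score_table"))
  table$functional_class <- assign_functional_class(table$mave_score, thresholds)
  if (any(!is.na(table$rsa))) {
    bin <- rep(NA_character_, nrow(table))
    ok <- !is.na(table$rsa)
    bin[ok] <- assign_rsa_bin(table$rsa[ok], binning)
    table$rsa_bin <- bin
  }
  table
}

#' Build the LoF/FUNC analysis cohort
#'
#' Drops intermediate (INT) variants — the association of partial functional
#' impairment with disease predisposition is unclear — keeping only LOF
#' (pathogenicity proxy) and FUNC (benignity proxy) records.
#'
#' @param table a classified `score_table` (no `UNASSIGNED` records).
#' @return the filtered `score_table`; attribute `class_counts` reports the
#'   LOF/INT/FUNC counts of the input.
#' @export
build_analysis_cohort <- function(table) {
  stopifnot(inherits(table, "score_table"))
  if (any(table$functional_class == "UNASSIGNED")) {
    stop("functional_class UNASSIGNED present; run classify_variants() first")
  }
  counts <- table(factor(table$functional_class, levels = c("LOF", "INT", "FUNC")))
  out <- table[table$functional_class %in% c("LOF", "FUNC"), , drop = FALSE]
  out <- as_score_table(as.data.frame(out),
                        provenance = paste0(attr(table, "provenance"),
                                            " | LoF/FUNC cohort"))
  if (nrow(out) == 0L) warning("analysis cohort is empty (no LOF or FUNC records)")
  attr(out, "class_counts") <- c(LOF = unname(counts["LOF"]),
                                 INT = unname(counts["INT"]),
                                 FUNC = unname(counts["FUNC"]))
  out
}
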