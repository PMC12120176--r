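# Three-zone likelihood-ratio engine.
#
# A computational score is split into a benignity zone, an uninformative
# ("gray") zone and a pathogenicity zone. Against a LoF/FUNC truth cohort,
# the likelihood ratio of a zone is
#
#     LR_zone = P(zone | LoF) / P(zone | FUNC)
#
# LR > 1 in the pathogenic zone is evidence toward pathogenicity (PP3);
# LR < 1 in the benign zone is evidence toward benignity (BP4). log2 LR maps
# onto the Bayesian point scale of the ACMG/AMP framework: points 1, 2, 4, 8
# correspond to Supporting, Moderate, Strong, Very strong.

POINT_TIERS <- c(1L, 2L, 4L, 8L)
TIER_NAMES <- c(`1` = "SUPPORTING", `2` = "MODERATE", `4` = "STRONG",
                `8` = "VERY_STRONG")

#' Define a three-zone score partition
#'
#' For a tool where higher scores indicate pathogenicity, scores at or below
#' `benign_cut` fall in the benignity zone, scores at or above `path_cut` in
#' the pathogenicity zone, and scores strictly between in the uninformative
#' gray zone. For `direction = "LOWER_IS_PATHOGENIC"` the comparisons mirror
#' (benign zone is `>= benign_cut`, pathogenic zone `<= path_cut`).
#'
#' @param tool name of the score column the zone applies to.
#' @param benign_cut benignity threshold (inclusive).
#' @param path_cut pathogenicity threshold (inclusive).
#' @param direction `"HIGHER_IS_PATHOGENIC"` (default) or
#'   `"LOWER_IS_PATHOGENIC"`.
#' @return a `three_zone` object. `benign_cut == path_cut` is allowed and
#'   yields an empty gray zone.
#' @export
three_zone <- function(tool, benign_cut, path_cut,
                       direction = c("HIGHER_IS_PATHOGENIC", "LOWER_IS_PATHOGENIC")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(benign_cut), is.finite(path_cut))
  if (direction == "HIGHER_IS_PATHOGENIC" && benign_cut > path_cut) {
    stop("benign_cut must be <= path_cut when higher scores are pathogenic")
  }
  if (direction == "LOWER_IS_PATHOGENIC" && path_cut > benign_cut) {
    stop("path_cut must be <= benign_cut when lower scores are pathogenic")
  }
  structure(list(tool = tool, benign_cut = benign_cut, path_cut = path_cut,
                 direction = direction),
            class = "three_zone")
}

zone_of <- function(score, zone) {
  if (zone$direction == "HIGHER_IS_PATHOGENIC") {
    ifelse(score <= zone$benign_cut, "benign",
           ifelse(score >= zone$path_cut, "path", "gray"))
  } else {
    ifelse(score >= zone$benign_cut, "benign",
           ifelse(score <= zone$path_cut, "path", "gray"))
  }
}

#' Count LoF/FUNC variants per score zone
#'
#' @param cohort a `score_table` restricted to LOF and FUNC variants.
#' @param zone a [three_zone]. Records missing the tool's score are excluded
#'   and their count reported in the result.
#' @return a `zone_counts` list with per-class zone counts, class totals, the
#'   gray fraction and the number of score-missing records excluded.
#' @export
count_zones <- function(cohort, zone) {
  stopifnot(inherits(cohort, "score_table"), inherits(zone, "three_zone"))
  if (nrow(cohort) == 0L) stop("empty cohort")
  extra <- setdiff(unique(cohort$functional_class), c("LOF", "FUNC"))
  if (length(extra)) {
    stop("cohort must contain only LOF/FUNC records; found: ",
         paste(extra, collapse = ", "))
  }
  if (!zone$tool %in% names(cohort)) stop("no score column: ", zone$tool)
  score <- cohort[[zone$tool]]
  keep <- !is.na(score)
  n_excluded <- sum(!keep)
  cls <- cohort$functional_class[keep]
  zn <- zone_of(score[keep], zone)
  tab <- table(factor(cls, levels = c("LOF", "FUNC")),
               factor(zn, levels = c("benign", "gray", "path")))
  counts <- list(
    lof_benign = tab["LOF", "benign"], lof_gray = tab["LOF", "gray"],
    lof_path = tab["LOF", "path"],
    func_benign = tab["FUNC", "benign"], func_gray = tab["FUNC", "gray"],
    func_path = tab["FUNC", "path"],
    n_lof = sum(tab["LOF", ]), n_func = sum(tab["FUNC", ]),
    n_excluded_missing = n_excluded, tool = zone$tool, zone = zone)
  counts$gray_fraction <- (counts$lof_gray + counts$func_gray) /
    (counts$n_lof + counts$n_func)
  structure(counts, class = "zone_counts")
}

#' Construct zone counts directly from integers
#'
#' Builds the per-zone count object from known counts (e.g. counts
#' reconstructed from a published sensitivity and zone total) without an
#' underlying cohort.
#'
#' @param lof_benign,lof_gray,lof_path LoF-class counts per zone.
#' @param func_benign,func_gray,func_path FUNC-class counts per zone.
#' @param tool tool name (descriptive).
#' @return a `zone_counts` object.
#' @export
zone_counts <- function(lof_benign, lof_gray, lof_path,
                        func_benign, func_gray, func_path, tool = "tool") {
  v <- c(lof_benign, lof_gray, lof_path, func_benign, func_gray, func_path)
  stopifnot(all(v >= 0))
  counts <- list(lof_benign = lof_benign, lof_gray = lof_gray,
                 lof_path = lof_path, func_benign = func_benign,
                 func_gray = func_gray, func_path = func_path,
                 n_lof = lof_benign + lof_gray + lof_path,
                 n_func = func_benign + func_gray + func_path,
                 n_excluded_missing = 0L, tool = tool, zone = NULL)
  counts$gray_fraction <- (lof_gray + func_gray) / (counts$n_lof + counts$n_func)
  structure(counts, class = "zone_counts")
}

#' Asymptotic confidence interval for a log2 likelihood ratio
#'
#' The LR is a ratio of two binomial proportions `x1/n1` over `x2/n2`; the
#' interval is computed on the natural-log scale as
#' `ln(LR) +/- z * sqrt((1 - p1)/x1 + (1 - p2)/x2)` and converted to log2.
#' When a numerator count is zero a Haldane-Anscombe correction (0.5 added to
#' all four counts) is applied and flagged via the `corrected` attribute.
#'
#' @param x1,n1 zone count and class total for the LoF (numerator) class.
#' @param x2,n2 zone count and class total for the FUNC (denominator) class.
#' @param level confidence level in (0, 1), default 0.95.
#' @return numeric `c(lo, hi)` on the log2 scale, attribute `corrected`.
#' @export
log2_lr_ci <- function(x1, n1, x2, n2, level = 0.95) {
  stopifnot(level > 0, level < 1, n1 > 0, n2 > 0, x1 <= n1, x2 <= n2)
  corrected <- FALSE
  if (x1 == 0 || x2 == 0) {
    x1 <- x1 + 0.5; x2 <- x2 + 0.5; n1 <- n1 + 1; n2 <- n2 + 1
    corrected <- TRUE
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  se_ln <- sqrt((1 - p1) / x1 + (1 - p2) / x2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- (log(p1 / p2) + c(-1, 1) * z * se_ln) / log(2)
  structure(ci, corrected = corrected)
}

lr_estimate <- function(x1, n1, x2, n2, level = 0.95) {
  corrected <- (x1 == 0 || x2 == 0)
  if (corrected) {
    lr <- ((x1 + 0.5) / (n1 + 1)) / ((x2 + 0.5) / (n2 + 1))
  } else {
    lr <- (x1 / n1) / (x2 / n2)
  }
  ci <- log2_lr_ci(x1, n1, x2, n2, level)
  structure(list(lr = lr, log2_lr = log2(lr),
                 ci95_log2 = as.numeric(ci),
                 x1 = x1, n1 = n1, x2 = x2, n2 = n2,
                 ci_level = level, corrected = corrected ||
                   isTRUE(attr(ci, "corrected"))),
            class = "lr_estimate")
}

#' @export
print.lr_estimate <- function(x, ...) {
  cat(sprintf("LR = %.3f, log2 LR = %+.3f (%+.3f to %+.3f)%s  [%d/%d vs %d/%d]\n",
              x$lr, x$log2_lr, x$ci95_log2[1], x$ci95_log2[2],
              if (x$corrected) " [continuity-corrected]" else "",
              x$x1, x$n1, x$x2, x$n2))
  invisible(x)
}

#' Likelihood ratio of the pathogenicity zone
#'
#' `LR = (lof_path/n_lof) / (func_path/n_func)`; values above 1 support
#' pathogenicity (PP3).
#'
#' @param counts a [count_zones] result.
#' @param level confidence level for the log2 CI.
#' @return an `lr_estimate`.
#' @export
lr_pathogenic <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "zone_counts"))
  if (counts$n_lof == 0 || counts$n_func == 0) {
    stop("need both LOF and FUNC observations")
  }
  lr_estimate(counts$lof_path, counts$n_lof, counts$func_path, counts$n_func,
              level)
}

#' Likelihood ratio of the benignity zone
#'
#' `LR = (lof_benign/n_lof) / (func_benign/n_func)`; values below 1 support
#' benignity (BP4).
#'
#' @inheritParams lr_pathogenic
#' @return an `lr_estimate`.
#' @export
lr_benign <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "zone_counts"))
  if (counts$n_lof == 0 || counts$n_func == 0) {
    stop("need both LOF and FUNC observations")
  }
  if (counts$lof_benign == 0 && counts$func_benign == 0) {
    stop("no benign-zone observations")
  }
  lr_estimate(counts$lof_benign, counts$n_lof, counts$func_benign,
              counts$n_func, level)
}

#' Map a likelihood ratio to an ACMG/AMP evidence strength
#'
#' The absolute log2 LR is snapped to the nearest member of the point scale
#' \{1, 2, 4, 8\} (ties to the lower tier); |log2 LR| below 0.5 — beneath the
#' rounding basin of a single point — yields no evidence. Optionally, an
#' estimate whose confidence interval includes 0 on the log2 scale is demoted
#' to no evidence regardless of its point value.
#'
#' @param estimate an `lr_estimate`.
#' @param require_ci_excludes_null if `TRUE`, return no evidence when the
#'   log2 CI contains 0.
#' @return an `evidence_strength` list with `direction`
#'   (`PATHOGENIC`/`BENIGN`/`NONE`), `strength`
#'   (`NONE`/`SUPPORTING`/`MODERATE`/`STRONG`/`VERY_STRONG`) and signed
#'   `points` (0, +-1, +-2, +-4, +-8; positive toward pathogenicity).
#' @export
map_strength <- function(estimate, require_ci_excludes_null = FALSE) {
  stopifnot(inherits(estimate, "lr_estimate"))
  none <- structure(list(direction = "NONE", strength = "NONE", points = 0L),
                    class = "evidence_strength")
  mag <- abs(estimate$log2_lr)
  if (mag < 0.5) return(none)
  if (require_ci_excludes_null &&
      estimate$ci95_log2[1] <= 0 && estimate$ci95_log2[2] >= 0) {
    return(none)
  }
  d <- abs(POINT_TIERS - mag)
  tier <- POINT_TIERS[which(d == min(d))[1]]  # ties resolve to the lower tier
  direction <- if (estimate$log2_lr > 0) "PATHOGENIC" else "BENIGN"
  structure(list(direction = direction,
                 strength = unname(TIER_NAMES[as.character(tier)]),
                 points = if (direction == "PATHOGENIC") tier else -tier),
            class = "evidence_strength")
}

#' Evaluate one tool's three-zone calibration on a cohort
#'
#' Composes [count_zones], [lr_pathogenic], [lr_benign] and [map_strength]
#' into the per-tool report: zone counts, both LR estimates with CIs, both
#' evidence strengths, and the gray (uninformative) fraction.
#'
#' @inheritParams count_zones
#' @param level confidence level.
#' @param require_ci_excludes_null passed to [map_strength].
#' @return a `tool_evaluation` list.
#' @export
evaluate_tool <- function(cohort, zone, level = 0.95,
                          require_ci_excludes_null = FALSE) {
  counts <- count_zones(cohort, zone)
  if (counts$n_lof == 0 || counts$n_func == 0) {
    stop("cohort is single-class after exclusions; need both LOF and FUNC")
  }
  lp <- lr_pathogenic(counts, level)
  lb <- lr_benign(counts, level)
  structure(list(tool = zone$tool, zone = zone, counts = counts,
                 lr_path = lp, lr_benign = lb,
                 strength_path = map_strength(lp, require_ci_excludes_null),
                 strength_benign = map_strength(lb, require_ci_excludes_null),
                 gray_fraction = counts$gray_fraction,
                 n_excluded_missing = counts$n_excluded_missing),
            class = "tool_evaluation")
}

#' @export
print.tool_evaluation <- function(x, ...) {
  cat(sprintf("Tool %s  [benign %s %g | pathogenic %s %g]\n", x$tool,
              if (x$zone$direction == "HIGHER_IS_PATHOGENIC") "<=" else ">=",
              x$zone$benign_cut,
              if (x$zone$direction == "HIGHER_IS_PATHOGENIC") ">=" else "<=",
              x$zone$path_cut))
  cat("  PP3 (", x$strength_path$strength, "): ", sep = ""); print(x$lr_path)
  cat("  BP4 (", x$strength_benign$strength, "): ", sep = ""); print(x$lr_benign)
  cat(sprintf("  uninformative: %.1f%% of %d variants\n",
              100 * x$gray_fraction, x$counts$n_lof + x$counts$n_func))
  invisible(x)
}

#' Exhaustive three-zone threshold search
#'
#' Evaluates every ordered threshold pair `(benign_cut <= path_cut)` on a
#' candidate grid, keeps pairs whose pathogenic and benign log2 LRs both reach
#' a minimum magnitude with confidence intervals excluding 0 and whose gray
#' fraction does not exceed a cap, and returns the Pareto front under
#' (maximise the weaker of the two |log2 LR|s, minimise the gray fraction),
#' ranked by achieved strength tier (the weaker side's point tier) and then
#' by gray fraction. This mirrors the trade-off of maximising evidence
#' strength while minimising the share of variants left uninformative.
#'
#' @param cohort LoF/FUNC `score_table`.
#' @param tool score column name.
#' @param candidate_grid ascending numeric vector of candidate thresholds;
#'   default: the empirical score deciles.
#' @param min_abs_log2_each_side minimum |log2 LR| required on both sides.
#' @param max_gray_fraction maximum uninformative fraction.
#' @param direction score orientation, as in [three_zone].
#' @param level confidence level.
#' @return data frame of Pareto-optimal threshold pairs with their
#'   evaluations (empty, with a `diagnostics` attribute, when no pair meets
#'   the constraints); attribute `all_pairs` holds the full grid evaluation.
#' @export
search_thresholds <- function(cohort, tool, candidate_grid = NULL,
                              min_abs_log2_each_side = 1,
                              max_gray_fraction = 0.25,
                              direction = "HIGHER_IS_PATHOGENIC",
                              level = 0.95) {
  if (is.null(candidate_grid)) {
    candidate_grid <- unname(stats::quantile(cohort[[tool]],
                                             probs = seq(0.1, 0.9, 0.1),
                                             na.rm = TRUE))
  }
  if (length(candidate_grid) == 0L) stop("empty candidate grid")
  if (is.unsorted(candidate_grid)) stop("candidate_grid must be ascending")
  pairs <- expand.grid(benign_cut = candidate_grid, path_cut = candidate_grid)
  pairs <- if (direction == "HIGHER_IS_PATHOGENIC") {
    pairs[pairs$benign_cut <= pairs$path_cut, ]
  } else {
    pairs[pairs$path_cut <= pairs$benign_cut, ]
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    zn <- three_zone(tool, pairs$benign_cut[i], pairs$path_cut[i], direction)
    # pairs leaving a zone empty in both classes carry no evidence; skip them
    ev <- tryCatch(evaluate_tool(cohort, zn, level,
                                 require_ci_excludes_null = TRUE),
                   error = function(e) NULL)
    if (is.null(ev)) return(NULL)
    data.frame(benign_cut = pairs$benign_cut[i], path_cut = pairs$path_cut[i],
               log2_lr_path = ev$lr_path$log2_lr,
               log2_lr_benign = ev$lr_benign$log2_lr,
               ci_lo_path = ev$lr_path$ci95_log2[1],
               ci_hi_benign = ev$lr_benign$ci95_log2[2],
               points_path = ev$strength_path$points,
               points_benign = ev$strength_benign$points,
               gray_fraction = ev$gray_fraction)
  })
  all <- do.call(rbind, rows)
  if (is.null(all) || nrow(all) == 0L) stop("no evaluable threshold pairs on grid")
  all$min_abs_log2 <- pmin(abs(all$log2_lr_path), abs(all$log2_lr_benign))
  ok <- all$points_path > 0 & all$points_benign < 0 &
    abs(all$log2_lr_path) >= min_abs_log2_each_side &
    abs(all$log2_lr_benign) >= min_abs_log2_each_side &
    all$gray_fraction <= max_gray_fraction
  feasible <- all[ok, , drop = FALSE]
  if (nrow(feasible) == 0L) {
    out <- feasible
    attr(out, "diagnostics") <- sprintf(
      "no threshold pair met |log2 LR| >= %g on both sides with gray <= %g (grid size %d)",
      min_abs_log2_each_side, max_gray_fraction, length(candidate_grid))
    attr(out, "all_pairs") <- all
    return(out)
  }
  # Pareto front: no other pair both strictly stronger (larger weaker-side
  # |log2 LR|) and strictly less gray.
  on_front <- vapply(seq_len(nrow(feasible)), function(i) {
    !any(feasible$min_abs_log2 >= feasible$min_abs_log2[i] &
           feasible$gray_fraction <= feasible$gray_fraction[i] &
           (feasible$min_abs_log2 > feasible$min_abs_log2[i] |
              feasible$gray_fraction < feasible$gray_fraction[i]))
  }, logical(1))
  front <- feasible[on_front, , drop = FALSE]
  front$tier <- pmin(front$points_path, -front$points_benign)
  front <- front[order(-front$tier, front$gray_fraction, -front$min_abs_log2), ]
  rownames(front) <- NULL
  attr(front, "all_pairs") <- all
  front
}
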