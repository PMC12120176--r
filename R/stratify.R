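# Stratified evidence: per-stratum LRs, tool-pair concordance, and the
# RSA -> pathogenicity score -> stability score cascade.

#' Define a stratum by a predicate over variant fields
#'
#' @param name stratum label.
#' @param predicate function taking a `score_table` and returning a logical
#'   vector selecting the stratum's rows.
#' @return a `stratum` object.
#' @export
stratum <- function(name, predicate) {
  stopifnot(is.character(name), is.function(predicate))
  structure(list(name = name, predicate = predicate), class = "stratum")
}

#' Standard RSA strata (buried / partially buried / exposed)
#'
#' @param binning an [rsa_binning] object.
#' @return list of three [stratum] objects partitioning any cohort with
#'   non-missing RSA.
#' @export
rsa_strata <- function(binning = rsa_binning()) {
  mk <- function(bin) {
    force(bin)
    stratum(bin, function(tb) assign_rsa_bin(tb$rsa, binning) == bin)
  }
  lapply(stats::setNames(RSA_BINS, RSA_BINS), mk)
}

check_partition <- function(cohort, strata) {
  hits <- vapply(strata, function(s) s$predicate(cohort),
                 logical(nrow(cohort)))
  if (nrow(cohort) == 1L) hits <- matrix(hits, nrow = 1L)
  n_hits <- rowSums(hits)
  if (any(n_hits != 1L)) {
    stop("strata do not partition the cohort: ",
         sum(n_hits == 0L), " rows unmatched, ",
         sum(n_hits > 1L), " rows matched more than once")
  }
  hits
}

#' Per-stratum three-zone evaluation
#'
#' Evaluates one tool's three-zone calibration separately within each
#' stratum. Strata whose pathogenic or benign CI spans 0 are flagged as
#' providing no statistically significant evidence on that side; strata with
#' fewer than two variants in either truth class are flagged as underpowered
#' (not errored).
#'
#' @param cohort LoF/FUNC `score_table`.
#' @param strata list of [stratum] objects that partition the cohort.
#' @param zone a [three_zone].
#' @param level confidence level.
#' @return named list of per-stratum results: each either a
#'   `tool_evaluation` (with `significant_path` / `significant_benign` flags
#'   attached) or a flag list for underpowered strata.
#' @export
stratified_evaluate <- function(cohort, strata, zone, level = 0.95) {
  stopifnot(inherits(cohort, "score_table"))
  hits <- check_partition(cohort, strata)
  out <- lapply(seq_along(strata), function(i) {
    sub <- as_score_table(as.data.frame(cohort[hits[, i], , drop = FALSE]),
                          provenance = paste0("stratum ", strata[[i]]$name))
    n_lof <- sum(sub$functional_class == "LOF")
    n_func <- sum(sub$functional_class == "FUNC")
    if (n_lof < 2 || n_func < 2) {
      return(list(stratum = strata[[i]]$name, underpowered = TRUE,
                  n_lof = n_lof, n_func = n_func))
    }
    ev <- evaluate_tool(sub, zone, level)
    ev$stratum <- strata[[i]]$name
    ev$significant_path <- ev$lr_path$ci95_log2[1] > 0
    ev$significant_benign <- ev$lr_benign$ci95_log2[2] < 0
    ev
  })
  stats::setNames(out, vapply(strata, `[[`, character(1), "name"))
}

#' Two-tool concordance evidence
#'
#' Partitions variants into both-pathogenic, both-benign, and
#' discordant-or-any-gray (treated as uninformative), and computes the LR of
#' each concordant category. Records missing either tool's score are
#' excluded and counted.
#'
#' @param cohort LoF/FUNC `score_table`.
#' @param zone_a,zone_b [three_zone] objects for the two tools.
#' @param level confidence level.
#' @return a `concordance_evaluation` list: both LR estimates (continuity
#'   corrected with a flag when a concordant category is empty in one class),
#'   category counts, and the uninformative fraction.
#' @export
concordance_evaluate <- function(cohort, zone_a, zone_b, level = 0.95) {
  stopifnot(inherits(cohort, "score_table"))
  sa <- cohort[[zone_a$tool]]
  sb <- cohort[[zone_b$tool]]
  keep <- !is.na(sa) & !is.na(sb)
  n_excluded <- sum(!keep)
  sub <- cohort[keep, , drop = FALSE]
  za <- zone_of(sa[keep], zone_a)
  zb <- zone_of(sb[keep], zone_b)
  cat3 <- ifelse(za == "path" & zb == "path", "both_path",
                 ifelse(za == "benign" & zb == "benign", "both_benign",
                        "uninformative"))
  cls <- sub$functional_class
  n_lof <- sum(cls == "LOF"); n_func <- sum(cls == "FUNC")
  if (n_lof == 0 || n_func == 0) stop("need both LOF and FUNC observations")
  cnt <- function(cat, cl) sum(cat3 == cat & cls == cl)
  lr_path <- lr_estimate(cnt("both_path", "LOF"), n_lof,
                         cnt("both_path", "FUNC"), n_func, level)
  lr_ben <- lr_estimate(cnt("both_benign", "LOF"), n_lof,
                        cnt("both_benign", "FUNC"), n_func, level)
  structure(list(
    tools = c(zone_a$tool, zone_b$tool),
    lr_path = lr_path, lr_benign = lr_ben,
    counts = table(factor(cat3, levels = c("both_benign", "uninformative",
                                           "both_path")),
                   factor(cls, levels = c("LOF", "FUNC"))),
    uninformative_fraction = mean(cat3 == "uninformative"),
    n_excluded_missing = n_excluded),
    class = "concordance_evaluation")
}

#' Build a cascade rule node
#'
#' A cascade rule is a small binary decision tree over variant fields
#' (numeric comparisons), with leaves naming evidence categories. Used to
#' combine RSA with a pathogenicity score and a stability score.
#'
#' @param field variant field or tool column name tested at this node.
#' @param comparator one of `"le"`, `"lt"`, `"ge"`, `"gt"`.
#' @param threshold numeric threshold.
#' @param yes,no subtree ([cascade_node]) or leaf label (character) followed
#'   when the comparison holds / fails.
#' @return a `cascade_node`.
#' @export
cascade_node <- function(field, comparator, threshold, yes, no) {
  comparator <- match.arg(comparator, c("le", "lt", "ge", "gt"))
  structure(list(field = field, comparator = comparator,
                 threshold = threshold, yes = yes, no = no),
            class = "cascade_node")
}

cascade_depth <- function(node) {
  if (!inherits(node, "cascade_node")) return(0L)
  1L + max(cascade_depth(node$yes), cascade_depth(node$no))
}

cascade_leaves <- function(node) {
  if (!inherits(node, "cascade_node")) return(node)
  c(cascade_leaves(node$yes), cascade_leaves(node$no))
}

#' Default RSA -> pathogenicity score -> stability score cascade
#'
#' Buried/partially buried variants (RSA <= 60) are routed through the
#' pathogenicity-score zones and then the stability-score zones, yielding
#' concordance-graded leaves; exposed variants can gain pathogenicity
#' evidence only (benignity evidence is withheld at the surface, where lack
#' of destabilisation does not guarantee functionality).
#'
#' @param am_tool,ddg_tool score column names.
#' @param am_benign,am_path pathogenicity-score thresholds.
#' @param ddg_benign,ddg_path stability-score thresholds (kcal/mol).
#' @param rsa_exposed_min RSA above which a residue counts as exposed.
#' @return a `cascade_node` tree of depth <= 4.
#' @export
default_cascade <- function(am_tool = "AM", ddg_tool = "DDG_AF",
                            am_benign = 0.65, am_path = 0.75,
                            ddg_benign = 1.5, ddg_path = 2.5,
                            rsa_exposed_min = 60) {
  cascade_node("rsa", "gt", rsa_exposed_min,
    yes = cascade_node(am_tool, "ge", am_path,
                       yes = "EXPOSED_PATH", no = "GRAY"),
    no = cascade_node(am_tool, "ge", am_path,
      yes = cascade_node(ddg_tool, "ge", ddg_path,
                         yes = "CORE_PATH_CONCORDANT", no = "CORE_PATH"),
      no = cascade_node(am_tool, "le", am_benign,
        yes = cascade_node(ddg_tool, "le", ddg_benign,
                           yes = "CORE_BENIGN_CONCORDANT", no = "CORE_BENIGN"),
        no = "GRAY")))
}

route_cascade <- function(record_row, node) {
  while (inherits(node, "cascade_node")) {
    v <- record_row[[node$field]]
    if (is.null(v) || is.na(v)) return(NA_character_)
    ok <- switch(node$comparator,
                 le = v <= node$threshold, lt = v < node$threshold,
                 ge = v >= node$threshold, gt = v > node$threshold)
    node <- if (ok) node$yes else node$no
  }
  node
}

#' Assign evidence through a cascade rule
#'
#' Routes every variant to exactly one leaf of the cascade tree, computes
#' each leaf's likelihood ratio on the calibration cohort (LoF vs FUNC zone
#' probabilities), maps leaf LRs to evidence strengths, and demotes leaves
#' whose CI spans 0 on the log2 scale to `GRAY` in the emitted assignments.
#' Variants missing a field used by the tree are assigned `GRAY` and counted.
#'
#' @param cohort LoF/FUNC `score_table` (the calibration cohort).
#' @param rule a `cascade_node` tree (depth <= 4), e.g. [default_cascade()].
#' @param level confidence level.
#' @return a `cascade_result` list: per-variant `assignments` data frame
#'   (variant_id, leaf, emitted label after demotion), per-leaf `leaf_lr`
#'   estimates and strengths, `gray_fraction` of emitted assignments, and
#'   `n_missing_field`.
#' @export
cascade_assign <- function(cohort, rule, level = 0.95) {
  stopifnot(inherits(cohort, "score_table"))
  if (cascade_depth(rule) > 4L) stop("cascade depth must be <= 4")
  leaves_declared <- unique(cascade_leaves(rule))
  leaf <- vapply(seq_len(nrow(cohort)),
                 function(i) route_cascade(cohort[i, , drop = FALSE], rule),
                 character(1))
  n_missing <- sum(is.na(leaf))
  leaf[is.na(leaf)] <- "GRAY"
  unreachable <- setdiff(leaves_declared, unique(leaf))
  if (length(unreachable)) {
    warning("unreachable leaf/leaves: ", paste(unreachable, collapse = ", "))
  }
  cls <- cohort$functional_class
  n_lof <- sum(cls == "LOF"); n_func <- sum(cls == "FUNC")
  if (n_lof == 0 || n_func == 0) stop("need both LOF and FUNC observations")
  leaf_names <- setdiff(unique(leaf), "GRAY")
  leaf_lr <- lapply(stats::setNames(leaf_names, leaf_names), function(lf) {
    est <- lr_estimate(sum(leaf == lf & cls == "LOF"), n_lof,
                       sum(leaf == lf & cls == "FUNC"), n_func, level)
    strength <- map_strength(est, require_ci_excludes_null = TRUE)
    list(estimate = est, strength = strength,
         demoted = strength$direction == "NONE")
  })
  emitted <- vapply(leaf, function(lf) {
    if (lf == "GRAY" || leaf_lr[[lf]]$demoted) "GRAY" else lf
  }, character(1))
  structure(list(
    assignments = data.frame(variant_id = cohort$variant_id, leaf = leaf,
                             emitted = unname(emitted),
                             stringsAsFactors = FALSE),
    leaf_lr = leaf_lr,
    gray_fraction = mean(emitted == "GRAY"),
    n_missing_field = n_missing),
    class = "cascade_result")
}
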