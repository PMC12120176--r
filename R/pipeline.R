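# Pipeline driver and report assembly. The analysis scripts under analysis/
# are thin wrappers over these functions.

#' Analysis configuration
#'
#' Bundles the functional-class thresholds, RSA binning, per-tool three-zone
#' thresholds, confidence level and seed used across a run.
#'
#' @param thresholds a [functional_thresholds].
#' @param binning an [rsa_binning].
#' @param zones named list of [three_zone] objects, one per tool.
#' @param ci_level confidence level in (0, 1).
#' @param seed integer seed.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(thresholds = functional_thresholds(),
                            binning = rsa_binning(),
                            zones = default_zones(),
                            ci_level = 0.95, seed = 1L) {
  stopifnot(ci_level > 0, ci_level < 1)
  structure(list(thresholds = thresholds, binning = binning, zones = zones,
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Default three-zone thresholds per tool
#'
#' Pathogenicity-score zones at 0.65/0.75, stability-change zones at
#' +1.5/+2.5 kcal/mol, meta-predictor zones at 0.15/0.28 (the thresholds in
#' clinical use for this gene).
#'
#' @return named list of [three_zone] objects.
#' @export
default_zones <- function() {
  list(AM = three_zone("AM", 0.65, 0.75),
       DDG_AF = three_zone("DDG_AF", 1.5, 2.5),
       DDG_PDB = three_zone("DDG_PDB", 1.5, 2.5),
       BD = three_zone("BD", 0.15, 0.28))
}

evaluation_row <- function(ev) {
  data.frame(tool = ev$tool,
             benign_cut = ev$zone$benign_cut, path_cut = ev$zone$path_cut,
             log2_lr_benign = ev$lr_benign$log2_lr,
             ci_lo_benign = ev$lr_benign$ci95_log2[1],
             ci_hi_benign = ev$lr_benign$ci95_log2[2],
             strength_benign = ev$strength_benign$strength,
             log2_lr_path = ev$lr_path$log2_lr,
             ci_lo_path = ev$lr_path$ci95_log2[1],
             ci_hi_path = ev$lr_path$ci95_log2[2],
             strength_path = ev$strength_path$strength,
             gray_fraction = ev$gray_fraction,
             stringsAsFactors = FALSE)
}

#' Run the calibration pipeline
#'
#' Executes the requested stages over a variant cohort — simulate (or load),
#' classify, calibrate (per-tool three-zone LRs), stratify (RSA strata and
#' cascade), evaluate (auROC, diagnostics), burden (carrier-count ORs) — and
#' writes one TSV per stage plus a JSON run manifest with a digest of every
#' emitted file. Identical config + seed + inputs produce identical outputs.
#'
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if absent).
#' @param stages character subset of
#'   `c("simulate", "classify", "calibrate", "stratify", "evaluate", "burden")`.
#' @param variant_table optional pre-loaded `score_table`; when `NULL` and
#'   the simulate stage is requested, a default synthetic cohort is generated
#'   with `config$seed`.
#' @param carrier_table optional path to a carrier-count TSV for the burden
#'   stage; defaults to the bundled per-stratum counts.
#' @return the run manifest (list), invisibly written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = analysis_config(), out_dir = "results",
                         stages = c("simulate", "classify", "calibrate",
                                    "stratify", "evaluate", "burden"),
                         variant_table = NULL, carrier_table = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_results_table(df, path)
    outputs <<- c(outputs, path)
    path
  }
  tb <- variant_table
  if ("simulate" %in% stages && is.null(tb)) {
    tb <- generate_mave_cohort(default_generator_config(seed = config$seed))
    emit(as.data.frame(tb), "simulated_cohort.tsv")
  }
  cohort <- NULL
  needs_cohort <- any(c("classify", "calibrate", "stratify", "evaluate")
                      %in% stages)
  if (needs_cohort && is.null(tb)) {
    stop("stage requires a variant table: none supplied")
  }
  if (needs_cohort) {
    tb <- classify_variants(tb, config$thresholds, config$binning)
    cohort <- build_analysis_cohort(tb)
    cc <- attr(cohort, "class_counts")
    emit(data.frame(class = names(cc), n = as.integer(cc)),
         "class_counts.tsv")
  }
  if ("calibrate" %in% stages) {
    zones <- config$zones[intersect(names(config$zones), tool_names(cohort))]
    calib <- do.call(rbind, lapply(zones, function(z) {
      evaluation_row(evaluate_tool(cohort, z, config$ci_level))
    }))
    emit(calib, "calibration.tsv")
  }
  if ("stratify" %in% stages) {
    strata <- rsa_strata(config$binning)
    zones <- config$zones[intersect(names(config$zones), tool_names(cohort))]
    strat <- do.call(rbind, lapply(zones, function(z) {
      per <- stratified_evaluate(cohort, strata, z, config$ci_level)
      do.call(rbind, lapply(names(per), function(nm) {
        ev <- per[[nm]]
        if (isTRUE(ev$underpowered)) {
          return(data.frame(tool = z$tool, stratum = nm, underpowered = TRUE,
                            log2_lr_benign = NA, log2_lr_path = NA,
                            significant_benign = NA, significant_path = NA,
                            gray_fraction = NA))
        }
        data.frame(tool = z$tool, stratum = nm, underpowered = FALSE,
                   log2_lr_benign = ev$lr_benign$log2_lr,
                   log2_lr_path = ev$lr_path$log2_lr,
                   significant_benign = ev$significant_benign,
                   significant_path = ev$significant_path,
                   gray_fraction = ev$gray_fraction)
      }))
    }))
    emit(strat, "stratified.tsv")
    if (all(c("AM", "DDG_AF") %in% tool_names(cohort))) {
      casc <- cascade_assign(cohort, default_cascade(), config$ci_level)
      leafs <- do.call(rbind, lapply(names(casc$leaf_lr), function(lf) {
        e <- casc$leaf_lr[[lf]]
        data.frame(leaf = lf, log2_lr = e$estimate$log2_lr,
                   ci_lo = e$estimate$ci95_log2[1],
                   ci_hi = e$estimate$ci95_log2[2],
                   strength = e$strength$strength, demoted = e$demoted)
      }))
      leafs <- rbind(leafs,
                     data.frame(leaf = "GRAY", log2_lr = NA, ci_lo = NA,
                                ci_hi = NA, strength = "NONE", demoted = NA))
      attr(leafs, "gray_fraction") <- casc$gray_fraction
      emit(leafs, "cascade_leaves.tsv")
    }
  }
  if ("evaluate" %in% stages) {
    lab <- cohort$functional_class == "LOF"
    evals <- do.call(rbind, lapply(tool_names(cohort), function(tl) {
      sc <- cohort[[tl]]
      keep <- !is.na(sc)
      data.frame(tool = tl,
                 auroc = compute_auroc(sc[keep], lab[keep])$auroc,
                 r_mave = pearson_r(sc[keep], cohort$mave_score[keep]))
    }))
    emit(evals, "discrimination.tsv")
  }
  burden_df <- NULL
  if ("burden" %in% stages) {
    path <- carrier_table %||% system.file("extdata",
                                           "bridges_carrier_counts.tsv",
                                           package = "pp3bp4")
    burden_df <- stratify_burden(read_carrier_table(path), config$ci_level)
    emit(burden_df, "burden.tsv")
  }
  manifest <- list(
    stages = stages,
    seed = config$seed,
    ci_level = config$ci_level,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    r_version = as.character(getRversion()),
    outputs = lapply(outputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Render a human-readable report from a run manifest
#'
#' Assembles the calibration (per-tool LR/strength/gray%), diagnostics and
#' burden sections that have results present in the manifest into one
#' markdown document; sections whose stage did not run are omitted.
#'
#' @param manifest a manifest list as returned by [run_pipeline()], or a path
#'   to a `manifest.json`.
#' @param path output markdown file; `NULL` returns the text invisibly.
#' @return the report text, invisibly.
#' @export
render_report <- function(manifest, path = NULL) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  lines <- c("# Computational evidence calibration report", "",
             sprintf("Run seed %s, confidence level %s, generated %s.",
                     manifest$seed, manifest$ci_level, manifest$timestamp), "")
  files <- vapply(manifest$outputs, function(o) o$path, character(1))
  for (o in manifest$outputs) {
    if (!file.exists(o$path)) stop("missing result referenced by manifest: ", o$path)
    digest <- unname(tools::md5sum(o$path))
    if (!identical(digest, o$md5)) stop("digest mismatch for ", o$path)
  }
  section <- function(file, title) {
    hit <- files[basename(files) == file]
    if (!length(hit)) return(NULL)
    df <- utils::read.delim(hit[1])
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste("##", title), "",
      paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | "), "")
  }
  lines <- c(lines,
             section("calibration.tsv", "Per-tool PP3/BP4 likelihood ratios"),
             section("stratified.tsv", "RSA-stratified evidence"),
             section("cascade_leaves.tsv", "Cascade evidence leaves"),
             section("discrimination.tsv", "Discrimination (auROC, correlation)"),
             section("burden.tsv", "Case-control burden (odds ratios)"))
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(text, path)
  invisible(text)
}
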