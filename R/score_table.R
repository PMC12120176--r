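#' @keywords internal
"_PACKAGE"

# Canonical per-variant columns; everything else in a score table is treated
# as a computational tool score column.
CORE_COLUMNS <- c("variant_id", "domain", "mave_score", "functional_class", "rsa")

FUNCTIONAL_CLASSES <- c("LOF", "INT", "FUNC", "UNASSIGNED")
DOMAIN_LEVELS <- c("RING", "BRCT", "OTHER")
RSA_BINS <- c("BURIED", "PARTIAL", "EXPOSED")

#' Construct a variant score table
#'
#' A score table is a data frame with one row per missense variant, carrying
#' the variant identifier, protein domain, MAVE functional score, assigned
#' functional class, relative solvent accessibility (RSA, in percent), and one
#' column per computational tool (pathogenicity scores in \[0, 1\],
#' free-energy changes in kcal/mol, meta-predictor scores unitless). Missing
#' tool scores are `NA`, never sentinel numbers.
#'
#' @param variant_id character vector of unique variant identifiers
#'   (e.g. protein-level HGVS).
#' @param domain protein domain label, one of `"RING"`, `"BRCT"`, `"OTHER"`.
#' @param mave_score numeric MAVE functional score (unitless).
#' @param rsa numeric relative solvent accessibility in percent; must be
#'   non-negative, values above 100 are permitted (normalised accessibility
#'   can exceed 100%).
#' @param functional_class one of `"LOF"`, `"INT"`, `"FUNC"`, `"UNASSIGNED"`.
#'   Defaults to `"UNASSIGNED"` until classification runs.
#' @param scores named list or data frame of computational score columns.
#' @param provenance free-text description of where the table came from.
#' @return an object of class `score_table` (a data frame).
#' @export
score_table <- function(variant_id, domain = "OTHER", mave_score = NA_real_,
                        rsa = NA_real_, functional_class = "UNASSIGNED",
                        scores = list(), provenance = "constructed in R") {
  variant_id <- as.character(variant_id)
  n <- length(variant_id)
  if (anyDuplicated(variant_id)) {
    dups <- unique(variant_id[duplicated(variant_id)])
    stop("duplicate variant_id: ", paste(dups, collapse = ", "))
  }
  domain <- as.character(domain)
  bad_dom <- setdiff(unique(domain), DOMAIN_LEVELS)
  if (length(bad_dom)) stop("invalid domain: ", paste(bad_dom, collapse = ", "))
  if (length(domain) == 1L) domain <- rep(domain, n)
  functional_class <- as.character(functional_class)
  if (length(functional_class) == 1L) functional_class <- rep(functional_class, n)
  bad <- setdiff(unique(functional_class), FUNCTIONAL_CLASSES)
  if (length(bad)) stop("invalid functional_class: ", paste(bad, collapse = ", "))
  rsa <- rep_len(as.numeric(rsa), n)
  if (any(rsa < 0, na.rm = TRUE)) stop("rsa must be >= 0")
  df <- data.frame(variant_id = variant_id, domain = domain,
                   mave_score = rep_len(as.numeric(mave_score), n),
                   functional_class = functional_class, rsa = rsa,
                   stringsAsFactors = FALSE)
  scores <- as.data.frame(scores, stringsAsFactors = FALSE)
  if (ncol(scores)) {
    stopifnot(nrow(scores) == n)
    df <- cbind(df, scores)
  }
  as_score_table(df, provenance = provenance)
}

#' Coerce a data frame to a score table
#'
#' @param df a data frame containing at least `variant_id` and `mave_score`.
#' @param provenance free-text provenance string.
#' @return a `score_table`.
#' @export
as_score_table <- function(df, provenance = attr(df, "provenance") %||% "coerced") {
  stopifnot(is.data.frame(df))
  missing_core <- setdiff(c("variant_id", "mave_score"), names(df))
  if (length(missing_core)) {
    stop("missing mandatory column(s): ", paste(missing_core, collapse = ", "))
  }
  if (anyDuplicated(df$variant_id)) {
    dups <- unique(df$variant_id[duplicated(df$variant_id)])
    stop("duplicate variant_id: ", paste(dups, collapse = ", "))
  }
  if (is.null(df$domain)) df$domain <- "OTHER"
  if (is.null(df$functional_class)) df$functional_class <- "UNASSIGNED"
  if (is.null(df$rsa)) df$rsa <- NA_real_
  if (any(df$rsa < 0, na.rm = TRUE)) stop("rsa must be >= 0")
  df <- df[, c(CORE_COLUMNS, setdiff(names(df), CORE_COLUMNS)), drop = FALSE]
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("score_table", "data.frame"))
}

#' List the computational tool columns of a score table
#'
#' @param table a `score_table`.
#' @return character vector of tool column names.
#' @export
tool_names <- function(table) setdiff(names(table), c(CORE_COLUMNS, "rsa_bin"))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table: %d variants, tools: %s>\n", nrow(x),
              paste(tool_names(x), collapse = ", ")))
  cat("provenance:", attr(x, "provenance"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

# Parse a character vector of numbers tolerantly: unicode minus U+2212 is
# accepted (printed tables use it), "", "NA", "NaN" become NA.
parse_numeric <- function(x) {
  x <- gsub("−", "-", trimws(as.character(x)))
  x[x %in% c("", "NA", "NaN")] <- NA
  suppressWarnings(as.numeric(x))
}

#' Read a tab-separated variant score table
#'
#' Reads a TSV file with a header row into a [score_table]. Column names in
#' the file are mapped onto the canonical fields through `column_map`; any
#' unmapped column is kept as a computational tool score column under its own
#' name. Numeric cells that cannot be parsed (after accepting unicode minus
#' and the missing-value spellings `""`, `"NA"`, `"NaN"`) become `NA`; their
#' count is reported in the `n_missing_cells` attribute. No rows are silently
#' dropped: `nrow(result)` equals the number of data rows in the file.
#'
#' @param path path to a TSV file with a header.
#' @param column_map named character vector mapping canonical field names
#'   (`variant_id`, `domain`, `mave_score`, `rsa`, `functional_class`, or a
#'   tool name) to the header used in the file, e.g.
#'   `c(variant_id = "id", mave_score = "mave", AM = "am_score")`.
#' @return a `score_table`; attributes `n_missing_cells` (count of
#'   unparseable/missing numeric cells) and `n_rows_in` are attached.
#' @export
read_variant_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    absent <- setdiff(unname(column_map), names(raw))
    if (length(absent)) {
      stop("column_map refers to absent column(s): ",
           paste(absent, collapse = ", "))
    }
    idx <- match(unname(column_map), names(raw))
    names(raw)[idx] <- names(column_map)
  }
  for (col in c("variant_id", "mave_score")) {
    if (!col %in% names(raw)) stop("missing mandatory column: ", col)
  }
  n_in <- nrow(raw)
  numeric_cols <- setdiff(names(raw),
                          c("variant_id", "domain", "functional_class", "rsa_bin"))
  n_missing <- 0L
  for (col in numeric_cols) {
    parsed <- parse_numeric(raw[[col]])
    n_missing <- n_missing + sum(is.na(parsed))
    raw[[col]] <- parsed
  }
  if (!"domain" %in% names(raw)) raw$domain <- "OTHER"
  if (!"functional_class" %in% names(raw)) raw$functional_class <- "UNASSIGNED"
  out <- as_score_table(raw, provenance = paste0("read from ", path))
  attr(out, "n_missing_cells") <- n_missing
  attr(out, "n_rows_in") <- n_in
  attr(out, "n_rows_kept") <- nrow(out)
  out
}

#' Write a results table as TSV
#'
#' Writes a collection of flat rows (a data frame, or a list of named lists
#' sharing one key set) to a tab-separated file with a header, at full
#' numeric precision (17 significant digits), so that a write/read round trip
#' preserves finite values to within 1e-12.
#'
#' @param rows data frame or list of named lists; all rows must share the
#'   same key set, and at least one row is required.
#' @param path output file path.
#' @return invisibly, the normalised data frame that was written.
#' @export
write_results_table <- function(rows, path) {
  if (is.data.frame(rows)) {
    df <- rows
  } else {
    if (length(rows) == 0L) stop("nothing to write: empty row collection")
    keys <- lapply(rows, function(r) sort(names(r)))
    if (!all(vapply(keys, identical, logical(1), keys[[1]]))) {
      stop("heterogeneous keys across rows")
    }
    df <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r[names(rows[[1]])], stringsAsFactors = FALSE)
    }))
  }
  if (nrow(df) == 0L) stop("nothing to write: empty row collection")
  fmt <- df
  for (col in names(fmt)) {
    if (is.numeric(fmt[[col]])) {
      fmt[[col]] <- ifelse(is.na(fmt[[col]]), "NA",
                           formatC(fmt[[col]], digits = 17, format = "g"))
    }
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
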