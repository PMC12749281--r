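# CSV ingestion and export for feature tables.
#
# Canonical schema (one row = one clinical feature in one disease context):
#   feature_id, feature_name, disease, category, source        -- metadata
#   tp, fp, fn, tn                                             -- counts quartet
#   prevalence, sensitivity, specificity, n_total              -- performance quartet
# A row must carry at least one complete quartet; when both are present and
# disagree beyond 1e-6 relative, counts win (with a warning).

schema_version <- "1.0"

meta_columns <- c("feature_id", "feature_name", "disease", "category", "source")
count_columns <- c("tp", "fp", "fn", "tn")
perf_columns <- c("prevalence", "sensitivity", "specificity", "n_total")

column_aliases <- list(
  feature_id = c("feature_id", "id", "feature id"),
  feature_name = c("feature_name", "feature", "name", "symptom", "feature name"),
  disease = c("disease", "condition", "diagnosis"),
  category = c("category", "type"),
  source = c("source", "review", "citation", "reference", "study"),
  tp = c("tp", "true_positives", "true positives"),
  fp = c("fp", "false_positives", "false positives"),
  fn = c("fn", "false_negatives", "false negatives"),
  tn = c("tn", "true_negatives", "true negatives"),
  prevalence = c("prevalence", "prev"),
  sensitivity = c("sensitivity", "sens"),
  specificity = c("specificity", "spec"),
  n_total = c("n_total", "n", "total", "total_patients", "total_n", "total patients")
)

#' Read a column-mapping configuration file
#'
#' Flat `canonical=actual` (or `canonical: actual`) lines mapping the
#' canonical schema names to the headers used in a particular CSV.
#' Blank lines and `#` comments are ignored.
#'
#' @param path Path to the config file.
#' @return Named character vector (canonical name -> actual header).
#' @export
read_column_map <- function(path) {
  if (!file.exists(path)) schema_error(sprintf("column-map file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  hit <- regexpr("[=:]", lines)
  if (any(hit < 0)) {
    schema_error(sprintf("cannot parse column-map line(s): %s",
                         paste(lines[hit < 0], collapse = "; ")))
  }
  keys <- trimws(substr(lines, 1L, hit - 1L))
  vals <- trimws(substring(lines, hit + 1L))
  unknown <- setdiff(keys, names(column_aliases))
  if (length(unknown)) {
    schema_error(sprintf("unknown canonical column(s) in map: %s",
                         paste(unknown, collapse = ", ")))
  }
  stats::setNames(vals, keys)
}

# Map raw CSV headers onto canonical names; user map wins over aliases.
resolve_columns <- function(headers, column_map = NULL) {
  lower <- tolower(trimws(headers))
  out <- stats::setNames(rep(NA_character_, length(column_aliases)),
                         names(column_aliases))
  for (canon in names(column_aliases)) {
    idx <- match(tolower(column_aliases[[canon]]), lower)
    idx <- idx[!is.na(idx)]
    if (length(idx)) out[[canon]] <- headers[idx[1L]]
  }
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      if (!column_map[[canon]] %in% headers) {
        schema_error(sprintf("column-map names '%s' for '%s' but the file has: %s",
                             column_map[[canon]], canon, paste(headers, collapse = ", ")))
      }
      out[[canon]] <- column_map[[canon]]
    }
  }
  out
}

# "12.5%" -> 0.125; "" / "NA" -> NA; otherwise as.numeric.
parse_numeric <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "na", "NaN")] <- NA
  pct <- !is.na(x) & grepl("%$", x)
  x[pct] <- sub("%$", "", x[pct])
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    validation_error(sprintf("non-numeric value(s): %s",
                             paste(unique(x[bad]), collapse = ", ")))
  }
  out[pct] <- out[pct] / 100
  out
}

#' Read a feature table from CSV
#'
#' Reads a CSV of clinical features (one row per feature per disease
#' context), matching headers case-insensitively against a built-in
#' alias map (e.g. `N`/`total`/`n_total`; `sens`/`sensitivity`),
#' optionally overridden by an explicit column map. Percent-formatted
#' values (`"85%"`) are divided by 100 on read; empty cells and `NA`
#' are missing.
#'
#' Each row must carry a complete counts quartet (tp, fp, fn, tn) or a
#' complete performance quartet (prevalence, sensitivity, specificity,
#' n_total). Rows with neither, or with invalid values, are rejected
#' with row-numbered diagnostics (collected in `attr(, "rejects")`,
#' reported as a warning) rather than aborting the read. When a row
#' carries both quartets they are cross-checked at 1e-6 relative
#' tolerance via [derive_counts()]; on mismatch the counts win and a
#' warning is issued.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param column_map Optional named character vector (canonical name ->
#'   actual header), e.g. from [read_column_map()].
#' @return An object of classes `feature_table` and `data.frame` with
#'   the canonical columns; provenance in attributes `source_file`,
#'   `read_time` and `schema_version`.
#' @examples
#' path <- system.file("extdata", "example_features.csv", package = "diagentropy")
#' ft <- read_feature_table(path)
#' nrow(ft)
#' @export
read_feature_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) schema_error(sprintf("input file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) schema_error(sprintf("empty table: %s", path))

  cols <- resolve_columns(names(raw), column_map)
  have_counts_cols <- all(!is.na(cols[count_columns]))
  have_perf_cols <- all(!is.na(cols[perf_columns]))
  if (!have_counts_cols && !have_perf_cols) {
    incomplete <- function(set) paste(set[is.na(cols[set])], collapse = ", ")
    schema_error(sprintf(
      paste0("no complete quartet of columns: counts quartet missing {%s}, ",
             "performance quartet missing {%s}; found headers: %s"),
      incomplete(count_columns), incomplete(perf_columns),
      paste(names(raw), collapse = ", ")
    ))
  }
  if (is.na(cols[["feature_id"]]) && is.na(cols[["feature_name"]])) {
    schema_error(sprintf(
      "no feature identifier column (feature_id or feature_name); found headers: %s",
      paste(names(raw), collapse = ", ")
    ))
  }

  pull_chr <- function(canon, default = NA_character_) {
    if (is.na(cols[[canon]])) rep(default, nrow(raw)) else trimws(raw[[cols[[canon]]]])
  }
  pull_num <- function(canon) {
    if (is.na(cols[[canon]])) rep(NA_real_, nrow(raw)) else parse_numeric(raw[[cols[[canon]]]])
  }

  ft <- data.frame(
    feature_id = pull_chr("feature_id"),
    feature_name = pull_chr("feature_name"),
    disease = pull_chr("disease", ""),
    category = pull_chr("category", "Other"),
    source = pull_chr("source", ""),
    tp = pull_num("tp"), fp = pull_num("fp"),
    fn = pull_num("fn"), tn = pull_num("tn"),
    prevalence = pull_num("prevalence"),
    sensitivity = pull_num("sensitivity"),
    specificity = pull_num("specificity"),
    n_total = pull_num("n_total"),
    stringsAsFactors = FALSE
  )
  no_id <- is.na(ft$feature_id) | !nzchar(ft$feature_id)
  ft$feature_id[no_id] <- sprintf("row_%04d", which(no_id))
  blank_name <- is.na(ft$feature_name) | !nzchar(ft$feature_name)
  ft$feature_name[blank_name] <- ft$feature_id[blank_name]
  if (anyDuplicated(ft$feature_id)) {
    dup <- unique(ft$feature_id[duplicated(ft$feature_id)])
    schema_error(sprintf("duplicated feature_id: %s", paste(dup, collapse = ", ")))
  }
  ft$category <- normalize_category(ft$category)

  rejects <- data.frame(row = integer(), feature_id = character(),
                        reason = character(), stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(ft))
  for (i in seq_len(nrow(ft))) {
    has_counts <- all(is.finite(unlist(ft[i, count_columns])))
    has_perf <- all(is.finite(unlist(ft[i, perf_columns])))
    if (!has_counts && !has_perf) {
      keep[i] <- FALSE
      rejects <- rbind(rejects, data.frame(
        row = i, feature_id = ft$feature_id[i],
        reason = "neither counts quartet nor performance quartet is complete",
        stringsAsFactors = FALSE
      ))
      next
    }
    checked <- tryCatch({
      if (has_counts) {
        cts <- diagnostic_counts(ft$tp[i], ft$fp[i], ft$fn[i], ft$tn[i])
        if (has_perf) {
          derived <- derive_counts(test_performance(
            ft$prevalence[i], ft$sensitivity[i], ft$specificity[i], ft$n_total[i]
          ))
          rel <- abs(unlist(derived[count_columns]) - unlist(cts[count_columns])) /
            pmax(cts$n_total * 1e-3, abs(unlist(cts[count_columns])))
          if (any(rel > 1e-6)) {
            warning(sprintf(
              "row %d (%s): counts and performance parameters disagree; using counts",
              i, ft$feature_id[i]
            ), call. = FALSE)
            # counts win: refresh the performance quartet from the counts
            perf <- tryCatch(counts_to_performance(cts), diagentropy_error = function(e) NULL)
            ft[i, perf_columns] <- if (is.null(perf)) NA_real_ else {
              c(perf$prevalence, perf$sensitivity, perf$specificity, perf$n_total)
            }
          }
        }
      } else {
        test_performance(ft$prevalence[i], ft$sensitivity[i],
                         ft$specificity[i], ft$n_total[i])
      }
      TRUE
    }, diagentropy_error = function(e) conditionMessage(e))
    if (!isTRUE(checked)) {
      keep[i] <- FALSE
      rejects <- rbind(rejects, data.frame(
        row = i, feature_id = ft$feature_id[i], reason = checked,
        stringsAsFactors = FALSE
      ))
    }
  }
  if (nrow(rejects)) {
    warning(sprintf("rejected %d row(s): %s", nrow(rejects),
                    paste(sprintf("row %d (%s)", rejects$row, rejects$reason),
                          collapse = "; ")), call. = FALSE)
  }
  ft <- ft[keep, , drop = FALSE]
  rownames(ft) <- NULL
  if (nrow(ft) == 0L) schema_error("no valid rows after validation")

  structure(
    ft,
    class = c("feature_table", "data.frame"),
    source_file = path,
    read_time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    schema_version = schema_version,
    rejects = if (nrow(rejects)) rejects else NULL
  )
}

#' Construct a feature table from a data frame
#'
#' In-memory counterpart of [read_feature_table()] for tables built
#' programmatically (e.g. by [generate_cohort()]). Columns are taken as
#' already canonical; missing metadata columns are filled with defaults.
#'
#' @param df Data frame with canonical columns (see
#'   [read_feature_table()]).
#' @return A `feature_table` object.
#' @export
as_feature_table <- function(df) {
  if (!is.data.frame(df)) validation_error("'df' must be a data frame")
  defaults <- list(
    feature_id = sprintf("row_%04d", seq_len(nrow(df))),
    feature_name = NULL, disease = "", category = "Other", source = "",
    tp = NA_real_, fp = NA_real_, fn = NA_real_, tn = NA_real_,
    prevalence = NA_real_, sensitivity = NA_real_, specificity = NA_real_,
    n_total = NA_real_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) {
      df[[nm]] <- if (nm == "feature_name") df$feature_id else defaults[[nm]]
    }
  }
  if (anyDuplicated(df$feature_id)) {
    validation_error("'feature_id' must be unique")
  }
  df <- df[, c(meta_columns, count_columns, perf_columns), drop = FALSE]
  structure(
    df,
    class = c("feature_table", "data.frame"),
    source_file = NA_character_,
    read_time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    schema_version = schema_version
  )
}

results_columns <- c(
  "feature_id", "feature_name", "disease", "category", "source",
  "n_total", "prevalence", "sensitivity", "specificity",
  "tp", "fp", "fn", "tn",
  "ppv", "npv", "youden_j", "dor", "log_dor",
  "h_parent_bits", "er_bits", "er_fraction", "quadrant"
)

#' Write a computed results table to CSV
#'
#' Serializes the output of [compute_feature_table()] with a fixed
#' column order and floats rounded to 6 significant digits; row order is
#' the input order. Missing values are written as empty cells.
#'
#' @param results Results data frame from [compute_feature_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  missing_cols <- setdiff(results_columns, names(results))
  if (length(missing_cols)) {
    schema_error(sprintf("results table missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  out <- results[, results_columns, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a computed results table from CSV
#'
#' Companion reader for files written by [write_results()].
#'
#' @param path Path to a results CSV.
#' @return Data frame with the standard results columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) schema_error(sprintf("results file not found: %s", path))
  res <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(c("youden_j", "er_fraction"), names(res))
  if (length(missing_cols)) {
    schema_error(sprintf("results file missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  res
}
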