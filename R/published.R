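# Published reference values from the study of 405 clinical features
# drawn from likelihood-ratio systematic reviews, used by the
# `replicate` command to compare a user-supplied copy of that source
# table against the published analysis.

#' Published reference values for the 405-feature analysis
#'
#' The headline numbers reported by the published analysis of 405
#' clinical features (symptoms, demographics, laboratory tests and
#' imaging findings) from 23 likelihood-ratio reviews: quadrant counts
#' at J >= 0.60 / ER >= 0.40, category counts, and Pearson correlations
#' of the entropy-removal percentage with each accuracy metric.
#' [replicate_study()] compares a recomputation of the source table
#' against these values.
#'
#' @return A list with `n_features`, `j_cut`, `er_cut`,
#'   `quadrant_counts`, `category_counts`, `correlations` and
#'   `spot_checks`.
#' @export
published_reference <- function() {
  list(
    n_features = 405L,
    j_cut = 0.60,
    er_cut = 0.40,
    quadrant_counts = c(
      HIGH_ACC_HIGH_INFO = 145L, HIGH_ACC_LOW_INFO = 32L,
      LOW_ACC_HIGH_INFO = 9L, LOW_ACC_LOW_INFO = 219L
    ),
    category_counts = c(
      "Demographics" = 3L, "Imaging" = 160L,
      "Lab/Diagnostic Tests" = 65L, "Signs/Symptoms/History" = 177L
    ),
    correlations = c(
      youden_j = 0.89, ppv = 0.74, sensitivity = 0.70,
      log_dor = 0.63, specificity = 0.50, npv = 0.43
    ),
    spot_checks = list(
      male_sex_hemorrhagic_stroke = list(er_fraction = 0.0041),
      ami_high_acc_low_info = list(youden_j = 0.72, er_fraction = 0.27)
    )
  )
}

#' Path to a local copy of the published source-data table
#'
#' The source table behind the published 405-feature analysis is
#' distributed as supplementary material / a public source-data
#' repository and is not bundled with this package. Users who have
#' downloaded it can point the package at their copy with
#' `options(diagentropy.source_data = "/path/to/table.csv")`;
#' replication helpers and tests look it up here.
#'
#' @return The configured path, or `""` if none is set.
#' @export
source_data_path <- function() {
  p <- getOption("diagentropy.source_data", "")
  if (is.null(p) || is.na(p)) "" else as.character(p)
}

#' Recompute the published analysis from a source table
#'
#' Runs the full pipeline (ingest, metrics, entropy removal, quadrants,
#' correlations) on a user-supplied copy of the published source-data
#' CSV and compares the results with [published_reference()].
#'
#' @param path Path to the source-data CSV.
#' @param column_map Optional column map for [read_feature_table()].
#' @param j_cut,er_cut Quadrant thresholds (published defaults).
#' @return An object of class `replication_report`: list with the
#'   computed `results`, `quadrants`, `correlations` and a `comparison`
#'   data frame of published vs computed values.
#' @export
replicate_study <- function(path, column_map = NULL, j_cut = 0.60, er_cut = 0.40) {
  ref <- published_reference()
  ft <- read_feature_table(path, column_map = column_map)
  res <- compute_feature_table(ft, j_cut = j_cut, er_cut = er_cut)
  qs <- quadrant_summary(res, j_cut = j_cut, er_cut = er_cut)
  cr <- correlation_report(res)

  rows <- list()
  for (q in names(ref$quadrant_counts)) {
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = paste0("quadrant_", q),
      published = as.numeric(ref$quadrant_counts[[q]]),
      computed = as.numeric(qs$quadrant_counts[q] %||% 0),
      stringsAsFactors = FALSE
    )
  }
  for (ct in names(ref$category_counts)) {
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = paste0("category_", gsub("[^A-Za-z]+", "_", ct)),
      published = as.numeric(ref$category_counts[[ct]]),
      computed = as.numeric(qs$category_counts[ct] %||% 0),
      stringsAsFactors = FALSE
    )
  }
  for (m in names(ref$correlations)) {
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = paste0("r_", m),
      published = as.numeric(ref$correlations[[m]]),
      computed = cr$r[cr$metric == m],
      stringsAsFactors = FALSE
    )
  }
  comparison <- do.call(rbind, rows)
  comparison$difference <- comparison$computed - comparison$published

  structure(
    list(results = res, quadrants = qs, correlations = cr,
         comparison = comparison, n = nrow(res)),
    class = "replication_report"
  )
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("<replication_report>  %d features recomputed\n", x$n))
  cat("  quantity                        published   computed   diff\n")
  for (i in seq_len(nrow(x$comparison))) {
    cat(sprintf("  %-30s %10.3f %10.3f %+8.3f\n",
                x$comparison$quantity[i], x$comparison$published[i],
                x$comparison$computed[i], x$comparison$difference[i]))
  }
  invisible(x)
}
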