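#' Compute accuracy metrics, entropy removal and quadrants for a table
#'
#' Runs the full per-feature pipeline over a feature table: fills in
#' whichever quartet is missing ([derive_counts()] /
#' [counts_to_performance()]), computes the conventional accuracy
#' metrics ([accuracy_metrics()]), the entropy decomposition
#' ([entropy_removal()]) and the quadrant label
#' ([classify_quadrant()]).
#'
#' Rows for which the computation is undefined — prevalence 0 or 1
#' (zero parent entropy), or an empty disease margin — are dropped from
#' the results and collected in `attr(, "rejects")` with their reason;
#' the run continues. The `dor`/`log_dor` columns carry the
#' Haldane--Anscombe-corrected value when a cell is zero
#' (`dor_corrected` flags those rows).
#'
#' @param ft A `feature_table` from [read_feature_table()],
#'   [as_feature_table()] or [generate_cohort()].
#' @param j_cut,er_cut Quadrant thresholds (defaults 0.60 and 0.40).
#' @return Data frame with the standard results columns (see
#'   [write_results()]) plus `dor_corrected`; per-row failures in
#'   `attr(, "rejects")`.
#' @examples
#' ft <- as_feature_table(data.frame(
#'   feature_id = "f1", feature_name = "worked example", category = "Imaging",
#'   tp = 160, fp = 80, fn = 40, tn = 720
#' ))
#' compute_feature_table(ft)
#' @export
compute_feature_table <- function(ft, j_cut = 0.60, er_cut = 0.40) {
  if (!is.data.frame(ft)) validation_error("'ft' must be a feature table / data frame")
  needed <- c(meta_columns, count_columns, perf_columns)
  missing_cols <- setdiff(needed, names(ft))
  if (length(missing_cols)) {
    schema_error(sprintf("feature table missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }

  rejects <- data.frame(feature_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  rows <- vector("list", nrow(ft))
  for (i in seq_len(nrow(ft))) {
    row <- ft[i, ]
    out <- tryCatch({
      cts <- if (all(is.finite(unlist(row[count_columns])))) {
        diagnostic_counts(row$tp, row$fp, row$fn, row$tn)
      } else if (all(is.finite(unlist(row[perf_columns])))) {
        derive_counts(test_performance(row$prevalence, row$sensitivity,
                                       row$specificity, row$n_total))
      } else {
        validation_error("no complete counts or performance quartet")
      }
      perf <- counts_to_performance(cts)
      met <- accuracy_metrics(cts, ppv_required = FALSE, npv_required = FALSE)
      ent <- entropy_removal(cts)
      q <- classify_quadrant(met$youden_j, ent$er_fraction, j_cut, er_cut)
      data.frame(
        feature_id = row$feature_id, feature_name = row$feature_name,
        disease = row$disease, category = row$category, source = row$source,
        n_total = cts$n_total, prevalence = perf$prevalence,
        sensitivity = perf$sensitivity, specificity = perf$specificity,
        tp = cts$tp, fp = cts$fp, fn = cts$fn, tn = cts$tn,
        ppv = met$ppv, npv = met$npv, youden_j = met$youden_j,
        dor = met$dor, log_dor = met$log_dor,
        h_parent_bits = ent$h_parent, er_bits = ent$er_bits,
        er_fraction = ent$er_fraction, quadrant = as.character(q),
        dor_corrected = met$dor_corrected,
        stringsAsFactors = FALSE
      )
    }, diagentropy_error = function(e) conditionMessage(e))
    if (is.character(out)) {
      rejects <- rbind(rejects, data.frame(
        feature_id = ft$feature_id[i], reason = out, stringsAsFactors = FALSE
      ))
      rows[[i]] <- NULL
    } else {
      rows[[i]] <- out
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) schema_error("no computable rows in the feature table")
  rownames(res) <- NULL
  if (nrow(rejects)) {
    warning(sprintf("%d row(s) could not be computed: %s", nrow(rejects),
                    paste(sprintf("%s (%s)", rejects$feature_id, rejects$reason),
                          collapse = "; ")), call. = FALSE)
  }
  attr(res, "rejects") <- if (nrow(rejects)) rejects else NULL
  attr(res, "j_cut") <- j_cut
  attr(res, "er_cut") <- er_cut
  res
}
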