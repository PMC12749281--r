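#' Two-tailed Pearson correlation
#'
#' Product-moment correlation with a two-tailed p-value from the t
#' statistic \eqn{t = r \sqrt{(n - 2) / (1 - r^2)}} on n - 2 degrees of
#' freedom (via [stats::cor.test()]). The p-value is returned at full
#' floating-point precision; presentation layers may render very small
#' values as "<0.0001".
#'
#' @param x,y Numeric vectors of equal length >= 3 with finite values
#'   and non-zero variance.
#' @return List with `r`, `p_two_tailed` and `n`.
#' @examples
#' pearson_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6))
#' @export
pearson_correlation <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) validation_error("'x' and 'y' must be numeric")
  if (length(x) != length(y)) {
    validation_error(sprintf("length mismatch: %d vs %d", length(x), length(y)))
  }
  if (length(x) < 3L) {
    degenerate_sample_error(sprintf("need at least 3 pairs, got %d", length(x)))
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    validation_error("'x' and 'y' must be finite")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    degenerate_variance_error("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_two_tailed = ct$p.value, n = length(x))
}

er_metric_names <- c(
  "youden_j", "ppv", "sensitivity", "specificity", "npv", "log_dor"
)

#' Correlate entropy removal with each accuracy metric
#'
#' For each of the six conventional accuracy metrics (Youden's J, PPV,
#' sensitivity, specificity, NPV and the logged diagnostic odds ratio),
#' computes the two-tailed Pearson correlation with the entropy-removal
#' fraction across the rows of a computed feature table.
#'
#' Rows with an undefined (non-finite) value for a metric are excluded
#' from that metric's correlation only (pairwise, not listwise), and
#' listed in the `excluded` attribute with a reason. The logged DOR uses
#' whatever `log_dor` column the table carries — by default the
#' Haldane--Anscombe-corrected value for tables with a zero cell, so
#' perfect tests stay in the correlation. A metric with fewer than 3
#' usable rows or zero variance gets an `error` entry; other metrics
#' are unaffected.
#'
#' @param results Data frame with an `er_fraction` column and the six
#'   metric columns (as produced by [compute_feature_table()]).
#' @param metrics Character vector of metric columns to correlate
#'   (default: all six).
#' @return An object of classes `correlation_report` and `data.frame`
#'   with columns `metric`, `r`, `p_two_tailed`, `n_used`, `error`;
#'   excluded rows in `attr(, "excluded")`.
#' @examples
#' ft <- generate_cohort(synth_config(n_features = 50, seed = 1))
#' rep <- correlation_report(compute_feature_table(ft))
#' rep
#' @export
correlation_report <- function(results, metrics = er_metric_names) {
  if (!is.data.frame(results)) validation_error("'results' must be a data frame")
  missing_cols <- setdiff(c("er_fraction", metrics), names(results))
  if (length(missing_cols)) {
    schema_error(sprintf("missing metric columns: %s", paste(missing_cols, collapse = ", ")))
  }
  ids <- if ("feature_id" %in% names(results)) {
    as.character(results$feature_id)
  } else {
    as.character(seq_len(nrow(results)))
  }

  er <- results$er_fraction
  excluded <- list()
  rows <- lapply(metrics, function(m) {
    y <- results[[m]]
    usable <- is.finite(er) & is.finite(y)
    if (any(!usable)) {
      excluded[[m]] <<- data.frame(
        feature_id = ids[!usable],
        metric = m,
        reason = sprintf("non-finite %s or er_fraction", m),
        stringsAsFactors = FALSE
      )
    }
    res <- tryCatch(
      pearson_correlation(er[usable], y[usable]),
      diagentropy_error = function(e) e
    )
    if (inherits(res, "error")) {
      data.frame(metric = m, r = NA_real_, p_two_tailed = NA_real_,
                 n_used = sum(usable), error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(metric = m, r = res$r, p_two_tailed = res$p_two_tailed,
                 n_used = res$n, error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else NULL
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' Format a p-value for display
#'
#' Values below 1e-4 are rendered as `"<0.0001"`, mirroring the common
#' reporting convention; larger values are shown to 4 decimals. The
#' underlying reports always carry full-precision p-values.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @examples
#' format_p_value(c(0.03, 1e-7))
#' @export
format_p_value <- function(p) {
  ifelse(is.na(p), "NA", ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p)))
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report>  er_fraction vs accuracy metrics\n")
  df <- as.data.frame(x)
  df$p <- format_p_value(df$p_two_tailed)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$error[i])) {
      cat(sprintf("  %-12s r = %+.4f  p = %s  n = %d\n",
                  df$metric[i], df$r[i], df$p[i], df$n_used[i]))
    } else {
      cat(sprintf("  %-12s ERROR: %s (n = %d)\n", df$metric[i], df$error[i], df$n_used[i]))
    }
  }
  ex <- attr(x, "excluded")
  if (!is.null(ex)) cat(sprintf("  (%d row-metric pairs excluded)\n", nrow(ex)))
  invisible(x)
}
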