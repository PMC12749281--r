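#' Diagnostic test performance parameters
#'
#' Bundles the four parameters from which a 2x2 diagnostic contingency
#' table can be reconstructed: disease prevalence in the study sample,
#' test sensitivity and specificity, and the total number of patients.
#'
#' @param prevalence Proportion of the sample with the target condition,
#'   in \[0, 1\].
#' @param sensitivity True-positive rate of the feature/test, in \[0, 1\].
#' @param specificity True-negative rate of the feature/test, in \[0, 1\].
#' @param n_total Total number of patients (positive, need not be integer).
#'
#' @return An object of class `test_performance`: a list with the four
#'   validated fields.
#' @examples
#' test_performance(0.2, 0.8, 0.9, 1000)
#' @export
test_performance <- function(prevalence, sensitivity, specificity, n_total) {
  check_proportion(prevalence, "prevalence")
  check_proportion(sensitivity, "sensitivity")
  check_proportion(specificity, "specificity")
  check_scalar_number(n_total, "n_total")
  if (n_total <= 0) {
    validation_error(sprintf("'n_total' must be > 0, got %g", n_total))
  }
  structure(
    list(
      prevalence = prevalence, sensitivity = sensitivity,
      specificity = specificity, n_total = n_total
    ),
    class = "test_performance"
  )
}

#' @export
print.test_performance <- function(x, ...) {
  cat("<test_performance>\n")
  cat(sprintf(
    "  prevalence = %g, sensitivity = %g, specificity = %g, N = %g\n",
    x$prevalence, x$sensitivity, x$specificity, x$n_total
  ))
  invisible(x)
}

#' 2x2 diagnostic counts
#'
#' A 2x2 contingency table for one dichotomous feature against disease
#' status. Cells may be fractional: counts derived from prevalence,
#' sensitivity and specificity are kept unrounded so that downstream
#' proportions are exact.
#'
#' @param tp,fp,fn,tn Non-negative cell counts (true/false positives,
#'   false/true negatives).
#'
#' @return An object of class `diagnostic_counts`: a list with the four
#'   cells plus the derived margins `n_positive = tp + fp` (test-positive
#'   node) and `n_negative = fn + tn` (test-negative node) and
#'   `n_total`.
#' @examples
#' diagnostic_counts(160, 80, 40, 720)
#' @export
diagnostic_counts <- function(tp, fp, fn, tn) {
  for (nm in c("tp", "fp", "fn", "tn")) {
    v <- get(nm)
    check_scalar_number(v, nm)
    if (v < 0) validation_error(sprintf("'%s' must be >= 0, got %g", nm, v))
  }
  total <- tp + fp + fn + tn
  if (total <= 0) validation_error("empty table: tp + fp + fn + tn must be > 0")
  structure(
    list(
      tp = tp, fp = fp, fn = fn, tn = tn,
      n_positive = tp + fp, n_negative = fn + tn, n_total = total
    ),
    class = "diagnostic_counts"
  )
}

#' @export
print.diagnostic_counts <- function(x, ...) {
  cat("<diagnostic_counts>\n")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("test+", "test-"), c("disease+", "disease-")))
  print(m)
  invisible(x)
}

#' Derive 2x2 counts from performance parameters
#'
#' Reconstructs the four contingency-table cells from prevalence,
#' sensitivity, specificity and total N:
#' \deqn{TP = prev \cdot sens \cdot N,\quad FP = (1-prev)(1-spec)N,}
#' \deqn{FN = prev (1-sens) N,\quad TN = (1-prev) \cdot spec \cdot N.}
#' Cells are not rounded; fractional counts are retained so that the
#' disease margin identities `tp + fn = prevalence * N` and
#' `fp + tn = (1 - prevalence) * N` hold exactly.
#'
#' @param perf A [test_performance()] object.
#' @return A [diagnostic_counts()] object.
#' @examples
#' derive_counts(test_performance(0.2, 0.8, 0.9, 1000))
#' @seealso [counts_to_performance()] for the inverse.
#' @export
derive_counts <- function(perf) {
  if (!inherits(perf, "test_performance")) {
    perf <- do.call(test_performance, as.list(perf)[c(
      "prevalence", "sensitivity", "specificity", "n_total"
    )])
  }
  p <- perf$prevalence; se <- perf$sensitivity
  sp <- perf$specificity; n <- perf$n_total
  diagnostic_counts(
    tp = p * se * n,
    fp = (1 - p) * (1 - sp) * n,
    fn = p * (1 - se) * n,
    tn = (1 - p) * sp * n
  )
}

#' Recover performance parameters from 2x2 counts
#'
#' Inverse of [derive_counts()]: prevalence, sensitivity and specificity
#' read off the margins of a contingency table. Requires both disease
#' margins to be non-empty.
#'
#' @param counts A [diagnostic_counts()] object.
#' @return A [test_performance()] object.
#' @examples
#' counts_to_performance(diagnostic_counts(160, 80, 40, 720))
#' @export
counts_to_performance <- function(counts) {
  stopifnot(inherits(counts, "diagnostic_counts"))
  diseased <- counts$tp + counts$fn
  healthy <- counts$fp + counts$tn
  if (diseased <= 0) {
    degenerate_margin_error("no diseased patients (tp + fn = 0): sensitivity undefined")
  }
  if (healthy <= 0) {
    degenerate_margin_error("no disease-negative patients (fp + tn = 0): specificity undefined")
  }
  test_performance(
    prevalence = diseased / counts$n_total,
    sensitivity = counts$tp / diseased,
    specificity = counts$tn / healthy,
    n_total = counts$n_total
  )
}

#' Conventional accuracy metrics from a 2x2 table
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' values, Youden's J (`sensitivity + specificity - 1`) and the
#' diagnostic odds ratio `DOR = (tp * tn) / (fp * fn)`.
#'
#' When any cell is exactly zero the raw DOR is 0, infinite or
#' undefined. In that case the Haldane--Anscombe continuity correction
#' (+0.5 on all four cells) is applied to obtain a finite `dor` and
#' `log_dor`, `dor_corrected` is set to `TRUE`, and the uncorrected
#' sentinel value (`Inf`, `0` or `NaN`) is kept in `dor_uncorrected`.
#'
#' @param counts A [diagnostic_counts()] object with both disease
#'   margins non-empty.
#' @param ppv_required,npv_required If `TRUE` (default), an empty test
#'   margin (`tp + fp = 0` or `tn + fn = 0`) raises a
#'   degenerate-margin error; otherwise the predictive value is `NaN`.
#' @return An object of class `accuracy_metrics`: a list with fields
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `youden_j`, `dor`,
#'   `log_dor` (natural log), `dor_corrected`, `dor_uncorrected`.
#' @examples
#' accuracy_metrics(diagnostic_counts(160, 80, 40, 720))
#' @export
accuracy_metrics <- function(counts, ppv_required = TRUE, npv_required = TRUE) {
  stopifnot(inherits(counts, "diagnostic_counts"))
  perf <- counts_to_performance(counts)

  if (counts$n_positive <= 0 && ppv_required) {
    degenerate_margin_error("no test-positive patients (tp + fp = 0): PPV undefined")
  }
  if (counts$n_negative <= 0 && npv_required) {
    degenerate_margin_error("no test-negative patients (fn + tn = 0): NPV undefined")
  }
  ppv <- if (counts$n_positive > 0) counts$tp / counts$n_positive else NaN
  npv <- if (counts$n_negative > 0) counts$tn / counts$n_negative else NaN

  cells <- c(counts$tp, counts$fp, counts$fn, counts$tn)
  dor_raw <- (counts$tp * counts$tn) / (counts$fp * counts$fn)
  corrected <- any(cells == 0)
  dor <- if (corrected) {
    ((counts$tp + 0.5) * (counts$tn + 0.5)) /
      ((counts$fp + 0.5) * (counts$fn + 0.5))
  } else {
    dor_raw
  }

  structure(
    list(
      sensitivity = perf$sensitivity,
      specificity = perf$specificity,
      ppv = ppv,
      npv = npv,
      youden_j = perf$sensitivity + perf$specificity - 1,
      dor = dor,
      log_dor = log(dor),
      dor_corrected = corrected,
      dor_uncorrected = dor_raw
    ),
    class = "accuracy_metrics"
  )
}

#' @export
print.accuracy_metrics <- function(x, ...) {
  cat("<accuracy_metrics>\n")
  cat(sprintf("  sensitivity = %.4f  specificity = %.4f\n", x$sensitivity, x$specificity))
  cat(sprintf("  ppv = %.4f  npv = %.4f  youden_j = %.4f\n", x$ppv, x$npv, x$youden_j))
  cat(sprintf("  dor = %.4g (log %.4g)%s\n", x$dor, x$log_dor,
              if (x$dor_corrected) "  [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}
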