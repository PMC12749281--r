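quadrant_levels <- c(
  "HIGH_ACC_HIGH_INFO", "HIGH_ACC_LOW_INFO",
  "LOW_ACC_HIGH_INFO", "LOW_ACC_LOW_INFO"
)

feature_categories <- c(
  "Demographics", "Imaging", "Lab/Diagnostic Tests", "Signs/Symptoms/History"
)

#' Assign accuracy-vs-information quadrants
#'
#' Places each feature in one of four quadrants by comparing Youden's J
#' (accuracy axis) and the entropy-removal fraction (information axis)
#' to threshold cutoffs. Both thresholds are inclusive on the high side:
#' `HIGH_ACC_HIGH_INFO` means `j >= j_cut` and `er_fraction >= er_cut`.
#'
#' @param j Numeric vector of Youden's J values in \[-1, 1\].
#' @param er_fraction Numeric vector of entropy-removal fractions in
#'   \[0, 1\] (same length as `j`, or either of length 1).
#' @param j_cut High-accuracy threshold on J (default 0.60).
#' @param er_cut High-information threshold on the ER fraction
#'   (default 0.40).
#' @return Factor with levels `HIGH_ACC_HIGH_INFO`, `HIGH_ACC_LOW_INFO`,
#'   `LOW_ACC_HIGH_INFO`, `LOW_ACC_LOW_INFO`.
#' @examples
#' classify_quadrant(0.72, 0.27)
#' classify_quadrant(c(0.6, -0.1), c(0.4, 0.0001))
#' @export
classify_quadrant <- function(j, er_fraction, j_cut = 0.60, er_cut = 0.40) {
  if (!is.numeric(j) || !is.numeric(er_fraction)) {
    validation_error("'j' and 'er_fraction' must be numeric")
  }
  n <- max(length(j), length(er_fraction))
  j <- rep_len(j, n)
  er_fraction <- rep_len(er_fraction, n)
  if (any(!is.finite(j)) || any(!is.finite(er_fraction))) {
    validation_error("'j' and 'er_fraction' must be finite (no NA/NaN/Inf)")
  }
  if (any(j < -1 | j > 1)) validation_error("'j' must lie in [-1, 1]")
  if (any(er_fraction < 0 | er_fraction > 1)) {
    validation_error("'er_fraction' must lie in [0, 1]")
  }
  check_scalar_number(j_cut, "j_cut")
  check_scalar_number(er_cut, "er_cut")

  lab <- ifelse(
    j >= j_cut,
    ifelse(er_fraction >= er_cut, "HIGH_ACC_HIGH_INFO", "HIGH_ACC_LOW_INFO"),
    ifelse(er_fraction >= er_cut, "LOW_ACC_HIGH_INFO", "LOW_ACC_LOW_INFO")
  )
  factor(lab, levels = quadrant_levels)
}

normalize_category <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(trimws(x))] <- "Other"
  idx <- match(tolower(trimws(x)), tolower(feature_categories))
  out <- ifelse(is.na(idx), NA_character_, feature_categories[idx])
  unknown <- is.na(out)
  if (any(unknown & x != "Other")) {
    warning(sprintf(
      "unknown feature categories tallied under 'Other': %s",
      paste(unique(x[unknown & x != "Other"]), collapse = ", ")
    ), call. = FALSE)
  }
  out[unknown] <- "Other"
  out
}

#' Quadrant and category tallies for a feature table
#'
#' Classifies every row of a computed feature table into a quadrant
#' (see [classify_quadrant()]) and tallies counts per quadrant and per
#' feature category. Categories are matched case-insensitively against
#' the four canonical names (Demographics, Imaging, Lab/Diagnostic
#' Tests, Signs/Symptoms/History); anything else is tallied under
#' `Other` with a warning.
#'
#' @param results Data frame with numeric columns `youden_j` and
#'   `er_fraction` and (optionally) a `category` column; typically the
#'   output of [compute_feature_table()].
#' @param j_cut,er_cut Thresholds passed to [classify_quadrant()].
#' @return An object of class `quadrant_summary`: a list with
#'   `quadrant_counts` (named integer vector over the four quadrants),
#'   `category_counts`, `n`, `j_cut` and `er_cut`.
#' @examples
#' res <- data.frame(youden_j = c(0.9, 0.7, 0.1), er_fraction = c(0.8, 0.1, 0.5),
#'                   category = c("Imaging", "Demographics", "Imaging"))
#' quadrant_summary(res)
#' @export
quadrant_summary <- function(results, j_cut = 0.60, er_cut = 0.40) {
  if (!is.data.frame(results)) validation_error("'results' must be a data frame")
  need <- c("youden_j", "er_fraction")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols)) {
    schema_error(sprintf("missing required columns: %s", paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!is.finite(results$youden_j) | !is.finite(results$er_fraction))
  if (length(bad)) {
    ids <- if ("feature_id" %in% names(results)) results$feature_id[bad] else bad
    validation_error(sprintf(
      "rows with missing/non-finite J or ER: %s", paste(ids, collapse = ", ")
    ))
  }

  q <- classify_quadrant(results$youden_j, results$er_fraction, j_cut, er_cut)
  qc <- table(q)

  cats <- if ("category" %in% names(results)) {
    normalize_category(results$category)
  } else {
    rep("Other", nrow(results))
  }
  cc <- table(factor(cats, levels = c(feature_categories, "Other")))
  cc <- cc[cc > 0 | names(cc) %in% feature_categories]

  structure(
    list(
      quadrant_counts = stats::setNames(as.integer(qc), names(qc)),
      category_counts = stats::setNames(as.integer(cc), names(cc)),
      n = nrow(results),
      j_cut = j_cut,
      er_cut = er_cut
    ),
    class = "quadrant_summary"
  )
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat(sprintf("<quadrant_summary>  n = %d  (J cut = %g, ER cut = %g)\n",
              x$n, x$j_cut, x$er_cut))
  for (q in names(x$quadrant_counts)) {
    cat(sprintf("  %-20s %d\n", q, x$quadrant_counts[[q]]))
  }
  cat("  categories:\n")
  for (ct in names(x$category_counts)) {
    cat(sprintf("    %-24s %d\n", ct, x$category_counts[[ct]]))
  }
  invisible(x)
}
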