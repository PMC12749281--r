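#' Shannon entropy of a discrete distribution
#'
#' \eqn{H(p) = -\sum_i p_i \log_2 p_i} in bits, with the usual
#' convention \eqn{0 \log 0 = 0}.
#'
#' @param p Numeric vector of probabilities: all components non-negative
#'   and summing to 1 (within 1e-9).
#' @return Entropy in bits, in `[0, log2(length(p))]`.
#' @examples
#' shannon_entropy(c(0.5, 0.5)) # 1 bit
#' shannon_entropy(c(0.2, 0.8))
#' @export
shannon_entropy <- function(p) {
  if (!is.numeric(p) || length(p) < 1L || any(!is.finite(p))) {
    validation_error("'p' must be a finite numeric vector")
  }
  if (any(p < 0)) {
    validation_error(sprintf("probabilities must be >= 0 (min was %g)", min(p)))
  }
  s <- sum(p)
  if (abs(s - 1) > 1e-9) {
    validation_error(sprintf("probabilities must sum to 1 (got %.12g)", s))
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy removed by a dichotomous diagnostic feature
#'
#' Frames the feature as a decision-tree split. The parent node is the
#' whole sample of N patients, with entropy taken over disease status
#' (prevalence vs 1 - prevalence). The child nodes are the test-positive
#' group (TP + FP patients) and the test-negative group (FN + TN
#' patients); each child's entropy is again over disease status within
#' the node. Entropy removal is the parent entropy minus the weighted
#' average child entropy, the weights being the node sizes
#' `n_positive / N` and `n_negative / N`:
#' \deqn{ER = H(parent) - \frac{n_+}{N} H(test+) - \frac{n_-}{N} H(test-).}
#' This equals the mutual information between the test and disease
#' indicators, so it is always non-negative; tiny negative values from
#' floating-point cancellation (above -1e-12) are clamped to 0.
#'
#' The headline quantity is `er_fraction = er_bits / h_parent`, the
#' proportion of baseline diagnostic uncertainty the feature removes
#' (reported as a fraction of 1; multiply by 100 for percent). It is
#' invariant to the logarithm base. An empty child node contributes zero
#' entropy with zero weight, so a perfect test (sensitivity =
#' specificity = 1) attains `er_fraction = 1`.
#'
#' @param counts A [diagnostic_counts()] object. Prevalence must be
#'   strictly inside (0, 1): with no diseased (or no healthy) patients
#'   the parent entropy is 0 and the removed fraction is undefined.
#' @return An object of class `entropy_result`: a list with `h_parent`,
#'   `h_positive`, `h_negative`, `h_children_weighted` (all bits),
#'   `er_bits` and `er_fraction`.
#' @examples
#' entropy_removal(diagnostic_counts(160, 80, 40, 720))
#' entropy_removal(diagnostic_counts(50, 0, 0, 50)) # perfect: fraction 1
#' @export
entropy_removal <- function(counts) {
  stopifnot(inherits(counts, "diagnostic_counts"))
  diseased <- counts$tp + counts$fn
  healthy <- counts$fp + counts$tn
  total <- counts$n_total
  if (diseased <= 0 || healthy <= 0) {
    zero_parent_entropy_error(
      "prevalence is 0 or 1: parent entropy is zero and the removed fraction is undefined"
    )
  }

  h_parent <- shannon_entropy(c(diseased, healthy) / total)
  node_entropy <- function(a, b) {
    n <- a + b
    if (n <= 0) 0 else shannon_entropy(c(a, b) / n)
  }
  h_positive <- node_entropy(counts$tp, counts$fp)
  h_negative <- node_entropy(counts$fn, counts$tn)
  h_children <- (counts$n_positive / total) * h_positive +
    (counts$n_negative / total) * h_negative

  er <- h_parent - h_children
  if (er < 0) {
    if (er < -1e-12) {
      validation_error(sprintf("negative entropy removal (%g): numerical failure", er))
    }
    er <- 0
  }

  structure(
    list(
      h_parent = h_parent,
      h_positive = h_positive,
      h_negative = h_negative,
      h_children_weighted = h_children,
      er_bits = er,
      er_fraction = er / h_parent
    ),
    class = "entropy_result"
  )
}

#' @export
print.entropy_result <- function(x, ...) {
  cat("<entropy_result>\n")
  cat(sprintf("  H(parent) = %.4f bits; H(test+) = %.4f; H(test-) = %.4f\n",
              x$h_parent, x$h_positive, x$h_negative))
  cat(sprintf("  weighted child entropy = %.4f bits\n", x$h_children_weighted))
  cat(sprintf("  entropy removed = %.4f bits (%.2f%% of parent)\n",
              x$er_bits, 100 * x$er_fraction))
  invisible(x)
}

#' Mutual information of a 2x2 joint distribution
#'
#' Independent cross-check for [entropy_removal()]: the information gain
#' of a binary split equals the mutual information
#' \eqn{I = \sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x) p(y)}}
#' between the test and disease indicators. Intended for tests and
#' validation, not as the computation path.
#'
#' @param joint 2x2 numeric matrix (rows: test status, columns: disease
#'   status) or length-4 vector `(p_tp, p_fp, p_fn, p_tn)`; entries
#'   non-negative and summing to 1 within 1e-9.
#' @return Mutual information in bits.
#' @examples
#' mutual_information(c(0.16, 0.08, 0.04, 0.72))
#' @export
mutual_information <- function(joint) {
  if (is.matrix(joint)) {
    if (!all(dim(joint) == c(2L, 2L))) validation_error("'joint' must be 2x2")
  } else {
    if (length(joint) != 4L) validation_error("'joint' must have 4 entries")
    joint <- matrix(joint, 2L, 2L, byrow = TRUE)
  }
  if (!is.numeric(joint) || any(!is.finite(joint)) || any(joint < 0)) {
    validation_error("'joint' entries must be finite and >= 0")
  }
  if (abs(sum(joint) - 1) > 1e-9) {
    validation_error(sprintf("'joint' must sum to 1 (got %.12g)", sum(joint)))
  }
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      pij <- joint[i, j]
      if (pij > 0) mi <- mi + pij * log2(pij / (px[i] * py[j]))
    }
  }
  max(mi, 0)
}
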