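# Synthetic cohort generator.
#
# Emulates the structure of a literature-derived table of ~405 clinical
# features: per row a category, a disease context (one of 23 synthetic
# review contexts), and a performance quartet (prevalence, sensitivity,
# specificity, N). Planted controls with analytically known entropy
# removal (perfect: fraction 1; independent: 0) make the whole pipeline
# testable by parameter recovery.

#' Configuration for the synthetic cohort generator
#'
#' @param n_features Number of feature rows to generate (default 405,
#'   the size of the real literature-derived table this emulates).
#' @param seed Integer seed (mandatory); identical configurations
#'   produce identical tables.
#' @param category_weights Named proportions over the four feature
#'   categories; default is the observed category mix
#'   3/405 Demographics, 160/405 Imaging, 65/405 Lab/Diagnostic Tests,
#'   177/405 Signs/Symptoms/History.
#' @param sens_shape,spec_shape Beta shape parameters `c(alpha, beta)`
#'   for sensitivity and specificity draws (default `c(5, 2)`, mean
#'   ~0.71, right-skewed toward clinically typical values).
#' @param prevalence_range Support of the uniform prevalence draw,
#'   bounded away from 0 and 1 so parent entropy is always positive
#'   (default `c(0.01, 0.60)`).
#' @param log10_n_range Total patient counts are drawn as
#'   `round(10^U(a, b))`; default `c(2, 3.5)`, i.e. 100 to ~3160
#'   patients per review.
#' @param n_planted_perfect Number of planted perfect features
#'   (sensitivity = specificity = 1, true ER fraction 1); default 5,
#'   mirroring the handful of perfect ultrasonographic features in the
#'   emulated table.
#' @param n_planted_independent Number of planted independent features
#'   (sensitivity = 1 - specificity exactly, true ER 0); default 5,
#'   standing in for near-uninformative demographic features.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_features = 405L,
                         seed,
                         category_weights = c(
                           "Demographics" = 3, "Imaging" = 160,
                           "Lab/Diagnostic Tests" = 65,
                           "Signs/Symptoms/History" = 177
                         ) / 405,
                         sens_shape = c(5, 2),
                         spec_shape = c(5, 2),
                         prevalence_range = c(0.01, 0.60),
                         log10_n_range = c(2, 3.5),
                         n_planted_perfect = 5L,
                         n_planted_independent = 5L) {
  if (missing(seed)) validation_error("'seed' is mandatory")
  check_scalar_number(seed, "seed")
  check_scalar_number(n_features, "n_features")
  if (n_features < 1) validation_error("'n_features' must be >= 1")
  if (length(category_weights) != 4L || any(category_weights < 0)) {
    validation_error("'category_weights' must be 4 non-negative proportions")
  }
  if (abs(sum(category_weights) - 1) > 1e-9) {
    validation_error("'category_weights' must sum to 1")
  }
  if (is.null(names(category_weights))) {
    names(category_weights) <- feature_categories
  }
  for (nm in c("sens_shape", "spec_shape")) {
    v <- get(nm)
    if (length(v) != 2L || any(!is.finite(v)) || any(v <= 0)) {
      validation_error(sprintf("'%s' must be two positive Beta shapes", nm))
    }
  }
  if (length(prevalence_range) != 2L || prevalence_range[1] <= 0 ||
      prevalence_range[2] >= 1 || prevalence_range[1] >= prevalence_range[2]) {
    validation_error("'prevalence_range' must be increasing and inside (0, 1)")
  }
  n_planted_perfect <- as.integer(n_planted_perfect)
  n_planted_independent <- as.integer(n_planted_independent)
  if (n_planted_perfect < 0 || n_planted_independent < 0) {
    validation_error("planted counts must be >= 0")
  }
  if (n_planted_perfect + n_planted_independent > n_features) {
    validation_error(sprintf(
      "planted rows (%d) exceed n_features (%d)",
      n_planted_perfect + n_planted_independent, n_features
    ))
  }
  structure(
    list(
      n_features = as.integer(n_features), seed = as.integer(seed),
      category_weights = category_weights,
      sens_shape = sens_shape, spec_shape = spec_shape,
      prevalence_range = prevalence_range, log10_n_range = log10_n_range,
      n_planted_perfect = n_planted_perfect,
      n_planted_independent = n_planted_independent
    ),
    class = "synth_config"
  )
}

# Analytic ground truth from the performance parameters: joint cell
# probabilities -> mutual information (a route independent of the
# parent/child decomposition used by entropy_removal()).
true_entropy_removal <- function(prevalence, sensitivity, specificity) {
  joint <- c(
    prevalence * sensitivity,
    (1 - prevalence) * (1 - specificity),
    prevalence * (1 - sensitivity),
    (1 - prevalence) * specificity
  )
  bits <- mutual_information(joint)
  h_parent <- shannon_entropy(c(prevalence, 1 - prevalence))
  list(er_bits = bits, er_fraction = bits / h_parent)
}

#' Generate a synthetic feature cohort
#'
#' Draws `n_features` synthetic clinical features according to a
#' [synth_config()]: a category (multinomial over the four canonical
#' categories), a prevalence, sensitivity, specificity and total N per
#' row (in that draw order), with each row assigned to one of 23
#' synthetic review contexts. Planted controls are drawn from a
#' separate sub-stream (seeded deterministically from the main seed) so
#' changing their number does not perturb the regular rows, and are
#' appended after the regular rows.
#'
#' Every row carries analytic ground truth — the entropy removal
#' implied by its generating parameters, computed via the
#' mutual-information route at generation time — in
#' `attr(, "ground_truth")`, for recovery testing with
#' [ground_truth_check()].
#'
#' @param config A [synth_config()].
#' @return A `feature_table` (performance quartet filled, counts left
#'   to [compute_feature_table()]) with a `ground_truth` attribute:
#'   a data frame of `feature_id`, `er_bits`, `er_fraction`, `planted`.
#' @examples
#' ft <- generate_cohort(synth_config(n_features = 20, seed = 1,
#'                                    n_planted_perfect = 2))
#' attr(ft, "ground_truth")[1:3, ]
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) {
    validation_error("'config' must be a synth_config object")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })

  n_reg <- config$n_features - config$n_planted_perfect - config$n_planted_independent
  cats <- names(config$category_weights)

  draw_rows <- function(n, id_prefix, name_prefix, planted) {
    if (n == 0L) return(NULL)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      category <- sample(cats, 1L, prob = config$category_weights)
      prevalence <- stats::runif(1L, config$prevalence_range[1], config$prevalence_range[2])
      if (planted == "perfect") {
        stats::runif(2L) # keep per-row draw count constant across row kinds
        sens <- 1
        spec <- 1
      } else if (planted == "independent") {
        stats::runif(1L)
        spec <- stats::rbeta(1L, config$spec_shape[1], config$spec_shape[2])
        sens <- 1 - spec
      } else {
        sens <- stats::rbeta(1L, config$sens_shape[1], config$sens_shape[2])
        spec <- stats::rbeta(1L, config$spec_shape[1], config$spec_shape[2])
      }
      n_total <- round(10^stats::runif(1L, config$log10_n_range[1], config$log10_n_range[2]))
      out[[i]] <- data.frame(
        feature_id = sprintf("%s%04d", id_prefix, i),
        feature_name = sprintf("%s %d", name_prefix, i),
        category = category,
        prevalence = prevalence, sensitivity = sens, specificity = spec,
        n_total = n_total,
        planted = planted,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  }

  set.seed(config$seed, kind = "Mersenne-Twister")
  regular <- draw_rows(n_reg, "SYN", "synthetic feature", "none")

  # planted sub-stream: a fixed offset keeps it disjoint from the main
  # stream while staying inside 32-bit integer range
  set.seed((config$seed + 999983L) %% .Machine$integer.max, kind = "Mersenne-Twister")
  perfect <- draw_rows(config$n_planted_perfect, "PERF", "planted perfect control", "perfect")
  indep <- draw_rows(config$n_planted_independent, "INDEP",
                     "planted independent control", "independent")

  all_rows <- rbind(regular, perfect, indep)
  k <- nrow(all_rows)
  context <- 1L + (seq_len(k) - 1L) %% 23L
  all_rows$disease <- sprintf("synthetic_condition_%02d", context)
  all_rows$source <- sprintf("synthetic_review_%02d", context)

  gt <- do.call(rbind, lapply(seq_len(k), function(i) {
    tr <- switch(all_rows$planted[i],
      perfect = list(
        er_bits = shannon_entropy(c(all_rows$prevalence[i], 1 - all_rows$prevalence[i])),
        er_fraction = 1
      ),
      independent = list(er_bits = 0, er_fraction = 0),
      true_entropy_removal(all_rows$prevalence[i], all_rows$sensitivity[i],
                           all_rows$specificity[i])
    )
    data.frame(feature_id = all_rows$feature_id[i], er_bits = tr$er_bits,
               er_fraction = tr$er_fraction, planted = all_rows$planted[i],
               stringsAsFactors = FALSE)
  }))

  ft <- as_feature_table(all_rows[, c(
    "feature_id", "feature_name", "disease", "category", "source",
    "prevalence", "sensitivity", "specificity", "n_total"
  )])
  attr(ft, "ground_truth") <- gt
  attr(ft, "synth_config") <- config
  ft
}

#' Check computed entropy removal against generator ground truth
#'
#' Compares the `er_fraction` computed by the pipeline with the
#' analytic ground truth stored by [generate_cohort()], row by row.
#'
#' @param ft A `feature_table` produced by [generate_cohort()] (must
#'   carry the `ground_truth` attribute).
#' @param results Results from [compute_feature_table()] on `ft`.
#' @param tol Maximum tolerated absolute deviation (default 1e-9).
#' @return An object of class `recovery_report`: list with `pass`,
#'   `max_deviation`, `n`, and a `failures` data frame naming any rows
#'   beyond tolerance.
#' @export
ground_truth_check <- function(ft, results, tol = 1e-9) {
  gt <- attr(ft, "ground_truth")
  if (is.null(gt)) {
    validation_error("feature table carries no ground-truth block (not from generate_cohort?)")
  }
  m <- merge(gt, results[, c("feature_id", "er_fraction")],
             by = "feature_id", suffixes = c("_true", "_computed"))
  if (nrow(m) == 0L) validation_error("no overlapping feature_id between table and results")
  m$deviation <- abs(m$er_fraction_computed - m$er_fraction_true)
  failures <- m[m$deviation >= tol,
                c("feature_id", "er_fraction_true", "er_fraction_computed", "deviation")]
  structure(
    list(
      pass = nrow(failures) == 0L,
      max_deviation = max(m$deviation),
      n = nrow(m),
      tol = tol,
      failures = failures
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report>  %s: %d rows, max |deviation| = %.3g (tol %.1g)\n",
              if (x$pass) "PASS" else "FAIL", x$n, x$max_deviation, x$tol))
  if (!x$pass) {
    cat(sprintf("  %d row(s) beyond tolerance, e.g. %s\n", nrow(x$failures),
                paste(utils::head(x$failures$feature_id, 5), collapse = ", ")))
  }
  invisible(x)
}
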