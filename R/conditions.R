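# Classed error conditions so callers (and tests) can distinguish failure
# modes without string matching.

de_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "diagentropy_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

validation_error <- function(msg) de_stop(msg, "validation_error", sys.call(-1))
degenerate_margin_error <- function(msg) de_stop(msg, "degenerate_margin_error", sys.call(-1))
zero_parent_entropy_error <- function(msg) de_stop(msg, "zero_parent_entropy_error", sys.call(-1))
degenerate_variance_error <- function(msg) de_stop(msg, "degenerate_variance_error", sys.call(-1))
degenerate_sample_error <- function(msg) de_stop(msg, "degenerate_sample_error", sys.call(-1))
schema_error <- function(msg) de_stop(msg, "schema_error", sys.call(-1))

check_scalar_number <- function(x, name, allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L) {
    validation_error(sprintf("'%s' must be a single number", name))
  }
  if (!allow_na && (is.na(x) || !is.finite(x))) {
    validation_error(sprintf("'%s' must be finite, got %s", name, format(x)))
  }
  invisible(x)
}

check_proportion <- function(x, name) {
  check_scalar_number(x, name)
  if (x < 0 || x > 1) {
    validation_error(sprintf("'%s' must lie in [0, 1], got %g", name, x))
  }
  invisible(x)
}
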