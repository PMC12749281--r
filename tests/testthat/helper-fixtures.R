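# Shared fixture builders. All fixtures are generated in code; CSVs are
# written to per-test temp files.

# Random valid 2x2 tables with both disease margins non-empty and
# prevalence strictly interior.
random_counts <- function(n, seed, max_cell = 1000) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    cells <- stats::runif(4, 0, max_cell)
    if (cells[1] + cells[3] > 0 && cells[2] + cells[4] > 0) {
      out[[i]] <- diagnostic_counts(cells[1], cells[2], cells[3], cells[4])
      i <- i + 1L
    }
  }
  out
}

# Direct-summation Pearson r and two-tailed p (textbook formula),
# independent of stats::cor.test.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Natural-log entropy-removal fraction, an independent route used to
# check base invariance.
er_fraction_nat_oracle <- function(counts) {
  h_nat <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  tot <- counts$n_total
  hp <- h_nat(c(counts$tp + counts$fn, counts$fp + counts$tn) / tot)
  node <- function(a, b) if (a + b <= 0) 0 else h_nat(c(a, b) / (a + b))
  hc <- (counts$n_positive / tot) * node(counts$tp, counts$fp) +
    (counts$n_negative / tot) * node(counts$fn, counts$tn)
  (hp - hc) / hp
}

write_feature_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
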