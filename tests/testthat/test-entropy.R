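test_that("shannon_entropy matches closed-form binary values", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(1, 0)), 0)
  # frozen from direct evaluation of -0.2 log2 0.2 - 0.8 log2 0.8
  expect_equal(shannon_entropy(c(0.2, 0.8)), 0.721928094887, tolerance = 1e-9)
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
})

test_that("shannon_entropy validates its probability vector", {
  expect_error(shannon_entropy(c(-0.1, 1.1)), class = "validation_error")
  expect_error(shannon_entropy(c(0.5, 0.6)), class = "validation_error")
  expect_error(shannon_entropy(c(0.5, NA)), class = "validation_error")
})

test_that("entropy removal handles perfect, independent and worked tables", {
  # perfect test: children are pure, all parent entropy removed
  perfect <- entropy_removal(diagnostic_counts(50, 0, 0, 50))
  expect_equal(perfect$er_fraction, 1, tolerance = 1e-12)
  expect_equal(perfect$er_bits, perfect$h_parent, tolerance = 1e-12)
  expect_equal(perfect$h_positive, 0)
  expect_equal(perfect$h_negative, 0)

  # split identical to parent: nothing removed
  indep <- entropy_removal(diagnostic_counts(25, 25, 25, 25))
  expect_equal(indep$er_bits, 0, tolerance = 1e-12)
  expect_equal(indep$er_fraction, 0, tolerance = 1e-12)

  # worked example, reference values frozen from the mutual-information
  # oracle evaluated before the implementation
  worked <- entropy_removal(diagnostic_counts(160, 80, 40, 720))
  expect_equal(worked$er_bits, 0.275458185536, tolerance = 1e-9)
  expect_equal(worked$er_fraction, 0.381559032660, tolerance = 1e-9)
  expect_equal(worked$h_parent, 0.721928094887, tolerance = 1e-9)
})

test_that("entropy result satisfies its internal identities", {
  for (cts in random_counts(50, seed = 7)) {
    er <- entropy_removal(cts)
    expect_equal(
      er$h_children_weighted,
      (cts$n_positive / cts$n_total) * er$h_positive +
        (cts$n_negative / cts$n_total) * er$h_negative,
      tolerance = 1e-12
    )
    expect_equal(er$er_bits, er$h_parent - er$h_children_weighted,
                 tolerance = 1e-12)
    expect_lte(er$h_parent, 1)
    expect_lte(er$h_positive, 1)
    expect_lte(er$h_negative, 1)
    expect_gte(er$er_bits, 0)
    expect_true(er$er_fraction >= 0 && er$er_fraction <= 1)
    # information gain is bounded by both the outcome and split entropies
    h_split <- shannon_entropy(c(cts$n_positive, cts$n_negative) / cts$n_total)
    expect_lte(er$er_bits, min(er$h_parent, h_split) + 1e-12)
  }
})

test_that("prevalence 0 or 1 is a zero-parent-entropy error", {
  expect_error(entropy_removal(diagnostic_counts(0, 10, 0, 90)),
               class = "zero_parent_entropy_error")
  expect_error(entropy_removal(diagnostic_counts(10, 0, 90, 0)),
               class = "zero_parent_entropy_error")
})

test_that("mutual information matches its closed-form cases", {
  expect_equal(mutual_information(rep(0.25, 4)), 0, tolerance = 1e-12)
  expect_equal(mutual_information(c(0.5, 0, 0, 0.5)), 1, tolerance = 1e-12)
  er <- entropy_removal(diagnostic_counts(160, 80, 40, 720))
  expect_equal(mutual_information(c(0.16, 0.08, 0.04, 0.72)), er$er_bits,
               tolerance = 1e-12)
  expect_error(mutual_information(c(0.5, 0.5, 0.5, 0.5)), class = "validation_error")
  expect_error(mutual_information(c(-0.1, 0.6, 0.3, 0.2)), class = "validation_error")
})

test_that("entropy removal equals the 2x2 mutual information on random tables", {
  for (cts in random_counts(2000, seed = 99)) {
    joint <- c(cts$tp, cts$fp, cts$fn, cts$tn) / cts$n_total
    expect_lt(abs(entropy_removal(cts)$er_bits - mutual_information(joint)), 1e-10)
  }
})

test_that("relabelling the test leaves entropy removal unchanged while J negates", {
  for (cts in random_counts(50, seed = 123)) {
    swapped <- diagnostic_counts(cts$fn, cts$tn, cts$tp, cts$fp)
    expect_equal(entropy_removal(swapped)$er_bits,
                 entropy_removal(cts)$er_bits, tolerance = 1e-12)
    expect_equal(counts_to_performance(swapped)$sensitivity +
                   counts_to_performance(swapped)$specificity - 1,
                 -(counts_to_performance(cts)$sensitivity +
                     counts_to_performance(cts)$specificity - 1),
                 tolerance = 1e-12)
  }
})

test_that("the removed fraction is invariant to the entropy base", {
  for (cts in random_counts(50, seed = 5)) {
    er <- entropy_removal(cts)
    if (er$er_fraction == 0) next
    expect_lt(abs(er$er_fraction - er_fraction_nat_oracle(cts)), 1e-12)
  }
})

test_that("removal is zero exactly when the test is independent of disease", {
  # along sens = 1 - spec the split carries no information
  for (spec in seq(0.05, 0.95, by = 0.09)) {
    for (prev in c(0.1, 0.3, 0.5)) {
      cts <- derive_counts(test_performance(prev, 1 - spec, spec, 1000))
      expect_lt(entropy_removal(cts)$er_bits, 1e-12)
    }
  }
  # off that line the removal is strictly positive
  for (delta in c(-0.2, -0.05, 0.05, 0.2)) {
    cts <- derive_counts(test_performance(0.3, 0.5 + delta, 0.5, 1000))
    expect_gt(entropy_removal(cts)$er_bits, 1e-6)
  }
})
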