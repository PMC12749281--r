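test_that("counts derive from performance parameters by the four margin formulas", {
  # perfect test at symmetric prevalence
  c1 <- derive_counts(test_performance(0.5, 1, 1, 100))
  expect_equal(unlist(c1[c("tp", "fp", "fn", "tn")]),
               c(tp = 50, fp = 0, fn = 0, tn = 50))

  # hand arithmetic: 0.2*0.8*1000, 0.8*0.1*1000, 0.2*0.2*1000, 0.8*0.9*1000
  c2 <- derive_counts(test_performance(0.2, 0.8, 0.9, 1000))
  expect_equal(c2$tp, 160)
  expect_equal(c2$fp, 80)
  expect_equal(c2$fn, 40)
  expect_equal(c2$tn, 720)
  expect_equal(c2$n_positive, 240)
  expect_equal(c2$n_negative, 760)

  # zero prevalence is a valid (degenerate) table at this layer
  c3 <- derive_counts(test_performance(0, 0.7, 0.9, 100))
  expect_equal(unlist(c3[c("tp", "fp", "fn", "tn")]),
               c(tp = 0, fp = 10, fn = 0, tn = 90))
})

test_that("fractional cells are retained and disease margins are conserved", {
  cts <- derive_counts(test_performance(0.123, 0.771, 0.888, 333))
  expect_false(cts$tp == round(cts$tp)) # no rounding
  expect_equal(cts$tp + cts$fn, 0.123 * 333, tolerance = 1e-12)
  expect_equal(cts$fp + cts$tn, (1 - 0.123) * 333, tolerance = 1e-12)
  expect_equal(cts$n_positive + cts$n_negative, cts$n_total)
})

test_that("invalid performance parameters are rejected naming the offending field", {
  expect_error(test_performance(1.2, 0.5, 0.5, 10), class = "validation_error")
  expect_error(test_performance(1.2, 0.5, 0.5, 10), "prevalence")
  expect_error(test_performance(0.5, -0.1, 0.5, 10), "sensitivity")
  expect_error(test_performance(0.5, 0.5, 2, 10), "specificity")
  expect_error(test_performance(0.5, 0.5, 0.5, 0), "n_total")
  expect_error(diagnostic_counts(-1, 0, 0, 10), class = "validation_error")
  expect_error(diagnostic_counts(0, 0, 0, 0), class = "validation_error")
})

test_that("counts_to_performance inverts derive_counts", {
  p1 <- counts_to_performance(diagnostic_counts(50, 0, 0, 50))
  expect_equal(p1$prevalence, 0.5)
  expect_equal(p1$sensitivity, 1)
  expect_equal(p1$specificity, 1)
  expect_equal(p1$n_total, 100)

  p2 <- counts_to_performance(diagnostic_counts(160, 80, 40, 720))
  expect_equal(p2$prevalence, 0.2, tolerance = 1e-12)
  expect_equal(p2$sensitivity, 0.8, tolerance = 1e-12)
  expect_equal(p2$specificity, 0.9, tolerance = 1e-12)

  # no disease-negative patients: specificity margin is empty
  expect_error(counts_to_performance(diagnostic_counts(10, 0, 5, 0)),
               class = "degenerate_margin_error")
  expect_error(counts_to_performance(diagnostic_counts(0, 5, 0, 5)),
               class = "degenerate_margin_error")
})

test_that("derive_counts / counts_to_performance round-trip is the identity", {
  set.seed(41)
  for (i in 1:200) {
    perf <- test_performance(runif(1, 0.01, 0.99), runif(1), runif(1),
                             runif(1, 1, 1e5))
    back <- counts_to_performance(derive_counts(perf))
    for (f in c("prevalence", "sensitivity", "specificity", "n_total")) {
      expect_equal(back[[f]], perf[[f]], tolerance = 1e-9)
    }
  }
})

test_that("accuracy metrics match hand arithmetic on the worked table", {
  m <- accuracy_metrics(diagnostic_counts(160, 80, 40, 720))
  expect_equal(m$ppv, 2 / 3, tolerance = 1e-12)
  expect_equal(m$npv, 720 / 760, tolerance = 1e-12)
  expect_equal(m$youden_j, 0.7, tolerance = 1e-12)
  expect_equal(m$dor, 36, tolerance = 1e-12)
  expect_equal(m$log_dor, log(36), tolerance = 1e-12)
  expect_false(m$dor_corrected)
  # youden_j is exactly sens + spec - 1
  expect_equal(m$youden_j, m$sensitivity + m$specificity - 1, tolerance = 1e-12)
})

test_that("zero cells trigger the Haldane-Anscombe correction with sentinel kept", {
  m <- accuracy_metrics(diagnostic_counts(50, 0, 0, 50))
  expect_equal(m$youden_j, 1)
  expect_true(m$dor_corrected)
  expect_identical(m$dor_uncorrected, Inf)
  expect_equal(m$dor, (50.5 * 50.5) / (0.5 * 0.5), tolerance = 1e-12)
  expect_equal(m$log_dor, log(m$dor))

  # useless test: all cells equal
  m0 <- accuracy_metrics(diagnostic_counts(25, 25, 25, 25))
  expect_equal(m0$youden_j, 0)
  expect_equal(m0$dor, 1)
  expect_equal(m0$log_dor, 0)

  expect_error(accuracy_metrics(diagnostic_counts(0, 0, 10, 10)),
               class = "degenerate_margin_error")
})

test_that("relabelling the test negates Youden's J and inverts the DOR", {
  set.seed(42)
  for (cts in random_counts(50, seed = 42)) {
    if (any(unlist(cts[c("tp", "fp", "fn", "tn")]) == 0)) next
    m <- accuracy_metrics(cts)
    swapped <- diagnostic_counts(cts$fn, cts$tn, cts$tp, cts$fp)
    ms <- accuracy_metrics(swapped)
    expect_equal(ms$youden_j, -m$youden_j, tolerance = 1e-12)
    expect_equal(ms$dor, 1 / m$dor, tolerance = 1e-9)
  }
})
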