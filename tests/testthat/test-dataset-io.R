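test_that("a performance-only table reads into records with lazy counts", {
  path <- write_feature_csv(data.frame(
    feature_id = c("a", "b", "c"), feature_name = c("A", "B", "C"),
    disease = "d", category = "Imaging", source = "s",
    prevalence = c(0.2, 0.3, 0.4), sensitivity = c(0.8, 0.7, 0.6),
    specificity = c(0.9, 0.85, 0.8), n_total = c(100, 200, 300)
  ))
  ft <- read_feature_table(path)
  expect_s3_class(ft, "feature_table")
  expect_equal(nrow(ft), 3L)
  expect_true(all(is.na(ft$tp)))
  expect_equal(ft$prevalence, c(0.2, 0.3, 0.4))
  expect_identical(attr(ft, "source_file"), path)
  expect_identical(attr(ft, "schema_version"), "1.0")
})

test_that("header aliases and percent values are handled on read", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "Feature,Condition,Type,Review,prev,Sens,Spec,N",
    "ultrasound,cond A,imaging,rev1,20%,85%,90%,500",
    "marker,cond B,lab/diagnostic tests,rev2,0.30,0.70,0.80,250"
  ), path)
  ft <- read_feature_table(path)
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$prevalence, c(0.20, 0.30))
  expect_equal(ft$sensitivity, c(0.85, 0.70))
  expect_equal(ft$n_total, c(500, 250))
  expect_equal(ft$category, c("Imaging", "Lab/Diagnostic Tests"))
  expect_equal(ft$feature_name, c("ultrasound", "marker"))
})

test_that("an explicit column map overrides unknown headers", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "sym,pv,se,sp,tot",
    "cough,0.25,0.6,0.7,400"
  ), path)
  expect_error(read_feature_table(path), class = "schema_error")
  map_path <- tempfile(fileext = ".cfg")
  writeLines(c(
    "# canonical = actual",
    "feature_name=sym", "prevalence=pv", "sensitivity: se",
    "specificity=sp", "n_total=tot"
  ), map_path)
  cmap <- read_column_map(map_path)
  ft <- read_feature_table(path, column_map = cmap)
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$prevalence, 0.25)

  bad_map <- tempfile(fileext = ".cfg")
  writeLines("not_a_column=x", bad_map)
  expect_error(read_column_map(bad_map), class = "schema_error")
})

test_that("counts win over inconsistent performance with a warning", {
  # performance implies tp = 0.2*0.8*1000 = 160; row claims 200 (off by 25%)
  path <- write_feature_csv(data.frame(
    feature_id = "x", feature_name = "X",
    tp = 200, fp = 80, fn = 40, tn = 680,
    prevalence = 0.2, sensitivity = 0.8, specificity = 0.9, n_total = 1000
  ))
  expect_warning(ft <- read_feature_table(path), "disagree")
  expect_equal(ft$tp, 200)
  # performance quartet refreshed from the counts
  expect_equal(ft$prevalence, 240 / 1000)
  expect_equal(ft$sensitivity, 200 / 240)
})

test_that("consistent dual-quartet rows read silently", {
  path <- write_feature_csv(data.frame(
    feature_id = "x", feature_name = "X",
    tp = 160, fp = 80, fn = 40, tn = 720,
    prevalence = 0.2, sensitivity = 0.8, specificity = 0.9, n_total = 1000
  ))
  expect_no_warning(ft <- read_feature_table(path))
  expect_equal(ft$sensitivity, 0.8)
})

test_that("schema and row-level failures are reported precisely", {
  # no complete quartet of columns at all
  path <- tempfile(fileext = ".csv")
  writeLines(c("feature_id,sensitivity,tp", "a,0.8,10"), path)
  err <- tryCatch(read_feature_table(path), schema_error = function(e) conditionMessage(e))
  expect_match(err, "tn")
  expect_match(err, "prevalence")

  # row-level: one row missing a value is rejected with its row number
  path2 <- write_feature_csv(data.frame(
    feature_id = c("a", "b"), feature_name = c("A", "B"),
    prevalence = c(0.2, NA), sensitivity = c(0.8, 0.7),
    specificity = c(0.9, 0.9), n_total = c(100, 100)
  ))
  expect_warning(ft2 <- read_feature_table(path2), "row 2")
  expect_equal(nrow(ft2), 1L)
  expect_equal(attr(ft2, "rejects")$row, 2L)

  expect_error(read_feature_table(tempfile()), class = "schema_error")
  empty <- tempfile(fileext = ".csv")
  writeLines("feature_id,tp,fp,fn,tn", empty)
  expect_error(read_feature_table(empty), class = "schema_error")

  dup <- write_feature_csv(data.frame(
    feature_id = c("a", "a"), feature_name = "A",
    tp = 1, fp = 1, fn = 1, tn = 1
  ))
  expect_error(read_feature_table(dup), class = "schema_error")
})

test_that("results serialize with the documented column order and round-trip", {
  ft <- as_feature_table(data.frame(
    feature_id = "p1", feature_name = "perfect", category = "Imaging",
    prevalence = 0.3, sensitivity = 1, specificity = 1, n_total = 100
  ))
  res <- compute_feature_table(ft)
  path <- tempfile(fileext = ".csv")
  write_results(res, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(gsub('"', "", header), c(
    "feature_id", "feature_name", "disease", "category", "source",
    "n_total", "prevalence", "sensitivity", "specificity",
    "tp", "fp", "fn", "tn", "ppv", "npv", "youden_j", "dor", "log_dor",
    "h_parent_bits", "er_bits", "er_fraction", "quadrant"
  ))
  back <- read_results(path)
  expect_equal(back$er_fraction, 1)
  expect_identical(back$quadrant, "HIGH_ACC_HIGH_INFO")

  # read-write-read idempotence at the serialized precision
  ft2 <- generate_cohort(synth_config(n_features = 25, seed = 2))
  res2 <- compute_feature_table(ft2)
  p1 <- tempfile(fileext = ".csv")
  write_results(res2, p1)
  r1 <- read_results(p1)
  p2 <- tempfile(fileext = ".csv")
  write_results(cbind(r1, dor_corrected = FALSE), p2)
  r2 <- read_results(p2)
  num <- vapply(r2, is.numeric, logical(1))
  for (col in names(r2)[num]) {
    expect_equal(r2[[col]], r1[[col]], tolerance = 1e-6)
  }
  expect_identical(r2$feature_id, res2$feature_id)
})

test_that("write_results refuses a table missing standard columns", {
  expect_error(write_results(data.frame(feature_id = "a"), tempfile()),
               class = "schema_error")
})
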