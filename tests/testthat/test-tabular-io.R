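test_that("WBC-dialect files parse with IDs dropped, labels recoded and missing cells masked", {
  path <- withr::local_tempfile(fileext = ".data")
  truth <- write_wbc_style_file(path, n = 12L, n_missing_rows = 2L)
  ds <- load_uci_table(path, dialect = "wbc")
  expect_equal(nrow(ds$features), truth$n)
  expect_equal(ncol(ds$features), 9L)
  expect_equal(sum(ds$missing_mask), truth$missing_cells)
  expect_equal(sum(ds$labels == 0L), truth$n_malignant)
  expect_equal(sum(ds$labels == 1L), truth$n_benign)
})

test_that("WDBC-dialect files parse with M/B recoded to 0/1 over 30 features", {
  path <- withr::local_tempfile(fileext = ".data")
  truth <- write_wdbc_style_file(path, n = 10L)
  ds <- load_uci_table(path, dialect = "wdbc")
  expect_equal(dim(ds$features), c(truth$n, 30L))
  expect_false(any(ds$missing_mask))
  expect_equal(sum(ds$labels == 0L), truth$n_malignant)
  expect_equal(sum(ds$labels == 1L), truth$n_benign)
})

test_that("malformed rows and unknown class codes are rejected with the line named", {
  path <- withr::local_tempfile(fileext = ".data")
  writeLines(c("1,1,1,1,1,1,1,1,1,1,2",
               "2,1,1,1,1,1,1,1,1,2"), path)   # second row short
  expect_error(load_uci_table(path, "wbc"), "line 2")
  writeLines(c("1,1,1,1,1,1,1,1,1,1,2",
               "2,1,1,1,1,1,1,1,1,1,7"), path)  # 7 is not a class code
  expect_error(load_uci_table(path, "wbc"), "class code")
})

test_that("a generic file with no missing marker has an all-false mask and round-trips through the writer", {
  ds <- toy_dataset(n = 15L, d = 4L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- load_uci_table(path, "generic", label_col = "class")
  expect_false(any(back$missing_mask))
  expect_equal(back$features, ds$features, tolerance = 1e-12)
  expect_equal(back$labels, ds$labels)
  # with a missing cell the mask round-trips too
  ds$features[3, 2] <- NA
  ds2 <- tabular_dataset(ds$features, ds$labels)
  write_dataset(ds2, path)
  back2 <- load_uci_table(path, "generic", label_col = "class")
  expect_equal(back2$missing_mask, ds2$missing_mask, ignore_attr = TRUE)
})

test_that("missing-value policies drop affected rows or impute the per-feature mean", {
  feats <- matrix(c(1, 2, 3, NA, 5, 6), 3, 2)
  ds <- tabular_dataset(feats, c(0L, 1L, 1L))
  dropped <- handle_missing(ds, "drop_rows")
  expect_equal(nrow(dropped$features), 2L)
  expect_false(any(dropped$missing_mask))
  imputed <- handle_missing(ds, "impute_mean")
  expect_equal(imputed$features[1, 2], mean(c(5, 6)), ignore_attr = TRUE)
  # 2x2 with a single observed value in the column: mean of one value is itself
  ds22 <- tabular_dataset(matrix(c(1, 2, NA, 7), 2, 2), c(0L, 1L))
  expect_equal(handle_missing(ds22, "impute_mean")$features[1, 2], 7,
               ignore_attr = TRUE)
  # untouched dataset passes through unchanged
  clean <- toy_dataset()
  expect_identical(handle_missing(clean, "drop_rows"), clean)
  # a fully missing feature cannot be imputed
  allna <- tabular_dataset(matrix(c(1, 2, NA, NA), 2, 2), c(0L, 1L))
  expect_error(handle_missing(allna, "impute_mean"), "entirely missing")
})

test_that("min-max normalization maps observed ranges onto [0,1] and constants to 0", {
  feats <- cbind(c(2, 4, 6), c(5, 5, 5), c(1, 10, 1))
  ds <- minmax_normalize(tabular_dataset(feats, c(0L, 1L, 1L)))
  expect_equal(ds$features[, 1], c(0, 0.5, 1))
  expect_equal(ds$features[, 2], c(0, 0, 0))
  expect_equal(ds$features[, 3], c(0, 1, 0))
  expect_true(ds$normalized)
  # property: every non-constant column attains both 0 and 1
  big <- minmax_normalize(toy_dataset(n = 30L, d = 5L))
  expect_equal(unname(apply(big$features, 2, min)), rep(0, 5))
  expect_equal(unname(apply(big$features, 2, max)), rep(1, 5))
})

test_that("splits use floor arithmetic, stay disjoint/exhaustive, stratify within one, and are seed-deterministic", {
  set.seed(33)
  ds <- tabular_dataset(matrix(rnorm(569 * 3), 569, 3),
                        labels = c(rep(0L, 212), rep(1L, 357)))
  parts <- split_dataset(ds, split_spec(seed = 4L))
  expect_equal(nrow(parts$test$features), 113L)        # floor(0.2 * 569)
  expect_equal(nrow(parts$validation$features), 91L)   # floor(0.2 * 456)
  expect_equal(nrow(parts$train$features), 365L)
  sizes <- vapply(parts, function(p) nrow(p$features), numeric(1))
  expect_equal(sum(sizes), 569)
  # stratification: benign share within 1 count of proportional
  for (p in parts) {
    expected <- 357 / 569 * length(p$labels)
    expect_lte(abs(sum(p$labels == 1L) - expected), 1)
  }
  # small-n floor arithmetic
  ds10 <- toy_dataset(n = 10L, d = 3L)
  p10 <- split_dataset(ds10, split_spec(seed = 1L))
  expect_equal(vapply(p10, function(p) nrow(p$features), numeric(1)),
               c(train = 7, validation = 1, test = 2))
  # determinism
  again <- split_dataset(ds, split_spec(seed = 4L))
  expect_identical(parts$test$features, again$test$features)
  expect_identical(parts$train$labels, again$train$labels)
})
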