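test_that("load_matrix reads CSVs, flags missing cells, validates ids", {
  dir <- withr::local_tempdir()
  mat_path <- file.path(dir, "m.csv")
  meta_path <- file.path(dir, "meta.csv")
  writeLines(c("entity_id,m1,m2",
               "h1,1.5,2",
               "h2,,3",
               "h3,0.5,1"), mat_path)
  writeLines(c("measure_id,domain,direction",
               "m1,process,higher_better",
               "m2,mortality,lower_better"), meta_path)
  qm <- load_matrix(mat_path, meta_path)
  expect_equal(sum(qm$observed), 5)
  expect_false(qm$observed["h2", "m1"])
  expect_equal(qm$values["h1", "m2"], 2)

  writeLines(c("entity_id,m1,m2", "h1,1,2", "h1,3,4"), mat_path)
  expect_error(load_matrix(mat_path, meta_path), "h1")

  writeLines(c("entity_id,m1,m2,m3", "h1,1,2,3"), mat_path)
  expect_error(load_matrix(mat_path, meta_path), "m3")

  writeLines(c("entity_id,m1,m2", "h1,abc,2"), mat_path)
  expect_error(load_matrix(mat_path, meta_path), "abc")
})

test_that("completeness filter drops sparse rows first, then sparse columns", {
  vals <- matrix(1, 10, 10)
  vals[1, 1:5] <- NA  # e01 observes 5/10
  m <- make_qm(vals)
  out <- filter_completeness(m)
  expect_setequal(out$entity_ids, sprintf("e%02d", 2:10))
  expect_equal(length(out$measure_ids), 10)

  vals <- matrix(1, 10, 10)
  vals[1:2, 1] <- NA  # m01 reported by 8/10, rows still at 9/10
  out <- filter_completeness(make_qm(vals))
  expect_equal(length(out$entity_ids), 10)
  expect_setequal(out$measure_ids, sprintf("m%02d", 2:10))
})

test_that("completeness filter: identity, bounds invariant, and empty error", {
  full <- make_qm(matrix(rnorm(30), 5, 6))
  out <- filter_completeness(full)
  expect_equal(out$values, full$values)

  # property: output always satisfies both bounds
  withr::with_seed(42, {
    for (rep in 1:10) {
      vals <- matrix(rnorm(200), 20, 10)
      vals[sample(length(vals), 60)] <- NA
      m <- make_qm(vals)
      out <- tryCatch(filter_completeness(m), error = function(e) NULL)
      if (is.null(out)) next
      expect_gte(min(rowMeans(out$observed)), 0.9)
      expect_gte(min(colMeans(out$observed)), 0.9)
    }
  })

  empty <- make_qm(matrix(c(1, NA, NA, NA, NA, 1), 2, 3))
  expect_error(filter_completeness(empty), "no entities survive")
})

test_that("orientation negates adverse measures and is idempotent", {
  vals <- matrix(c(0.1, 0.2, 1, 2), 2, 2)
  m <- make_qm(vals, domain = c("mortality", "process"),
               direction = c("lower_better", "higher_better"))
  out <- orient_measures(m)
  expect_equal(unname(out$values[, 1]), c(-0.1, -0.2))
  expect_equal(unname(out$values[, 2]), c(1, 2))
  expect_true(all(out$meta$direction == "higher_better"))
  expect_equal(orient_measures(out)$values, out$values)

  bad <- make_qm(vals, direction = "sideways")
  expect_error(orient_measures(bad), "sideways")
})

test_that("standardization gives exact z-scores with sample SD", {
  m <- make_qm(matrix(c(1, 2, 3), 3, 1))
  out <- standardize_measures(m)
  expect_equal(unname(out$values[, 1]), c(-1, 0, 1))

  withr::with_seed(9, {
    m <- make_qm(matrix(rexp(60), 12, 5))
    out <- standardize_measures(m)
    expect_lt(max(abs(colMeans(out$values))), 1e-9)
    expect_lt(max(abs(apply(out$values, 2, sd) - 1)), 1e-9)
  })

  const <- make_qm(matrix(c(5, 5, 5), 3, 1))
  expect_error(standardize_measures(const), "m01")
})

test_that("standardization is equivariant to affine rescaling of raw columns", {
  withr::with_seed(5, {
    x <- rnorm(10)
    a <- standardize_measures(make_qm(matrix(x, 10, 1)))
    b <- standardize_measures(make_qm(matrix(3.7 * x + 11, 10, 1)))
    expect_equal(a$values, b$values, tolerance = 1e-12)
  })
})

test_that("rank-based normal-scores transform is available behind the config", {
  cfg <- pipeline_config(standardize_method = "normal_scores")
  m <- make_qm(matrix(rexp(40), 20, 2))
  out <- standardize_measures(m, cfg)
  expect_lt(max(abs(colMeans(out$values))), 1e-9)
  # ranks preserved
  expect_equal(order(out$values[, 1]), order(m$values[, 1]))
})

test_that("winsorization clamps to +/- clip_sd without re-standardizing", {
  m <- make_qm(matrix(c(5.2, -7, 3.9, 0), 2, 2), standardized = TRUE)
  out <- clip_extremes(m)
  expect_equal(unname(out$values[1, 1]), 4)
  expect_equal(unname(out$values[2, 1]), -4)
  expect_equal(unname(out$values[1, 2]), 3.9)
  expect_error(clip_extremes(make_qm(matrix(1, 2, 2))), "standardized")
})

test_that("imputation fills unobserved cells with 0 and keeps the mask", {
  vals <- matrix(rnorm(20), 5, 4)
  vals <- scale(vals)[, ]  # standardized
  vals[2, 3] <- NA
  m <- make_qm(vals, standardized = TRUE, clipped = TRUE)
  out <- impute_missing(m)
  expect_equal(unname(out$values[2, 3]), 0)
  expect_false(out$observed[2, 3])
  expect_lt(max(abs(colMeans(out$values[, -3]) -
                      colMeans(vals[, -3], na.rm = TRUE))), 1e-9)

  full <- make_qm(matrix(rnorm(10), 5, 2), standardized = TRUE)
  expect_equal(impute_missing(full)$values, full$values)
})

test_that("preprocessing is deterministic end to end", {
  syn <- generate_synthetic(synthetic_spec(n_entities = 60, n_measures = 21,
                                           seed = 4))
  a <- preprocess(syn$matrix)
  b <- preprocess(syn$matrix)
  expect_identical(a$values, b$values)
  expect_identical(a$observed, b$observed)
})
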