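test_that("forward-fill imputation fills from the nearest preceding value", {
  df <- data.frame(a = c(3, NA, 5), b = c(7, NA, NA), c = 1:3)
  out <- pad_interpolate(df)
  expect_equal(out$a, c(3, 3, 5))
  expect_equal(out$b, c(7, 7, 7))
  expect_equal(out$c, 1:3)  # untouched column is the identity

  # longer runs match the brute-force scan oracle
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(30)
    x[sample(2:30, 8)] <- NA
    expect_equal(pad_interpolate(data.frame(x = x))$x, oracle_ffill(x))
  }
  expect_equal(pad_interpolate(data.frame(x = c(7, NA, NA, 2)))$x, c(7, 7, 7, 2))
})

test_that("a leading missing value is a schema error naming the column", {
  df <- data.frame(age = c(NA, 3), chol = c(1, 2))
  expect_error(pad_interpolate(df), "age")
})

test_that("forward-fill is idempotent", {
  set.seed(5)
  x <- rnorm(50); x[sample(2:50, 12)] <- NA
  once <- pad_interpolate(data.frame(x = x))
  expect_identical(pad_interpolate(once), once)
})

test_that("duplicate removal keeps first occurrences and counts removals", {
  df <- data.frame(a = c(1, 1), b = c(2, 2))
  out <- drop_duplicates(df)
  expect_equal(nrow(out$table), 1)
  expect_equal(out$removed_count, 1)

  distinct <- data.frame(a = 1:5, b = 5:1)
  out2 <- drop_duplicates(distinct)
  expect_equal(out2$removed_count, 0)
  expect_equal(out2$table, distinct)

  base <- data.frame(a = 1:10, b = rnorm(10))
  tripled <- base[rep(1:10, 3), ]
  out3 <- drop_duplicates(tripled)
  expect_equal(nrow(out3$table), 10)
  expect_equal(out3$removed_count, 20)
  # relative order of kept rows preserved
  expect_equal(out3$table$a, 1:10)
  # idempotence
  expect_equal(drop_duplicates(out3$table)$removed_count, 0)
})

test_that("IQR fences follow the linear-interpolation quartile convention", {
  b <- iqr_bounds(c(1, 2, 3, 4, 100))
  expect_equal(b$q1, oracle_quartile(c(1, 2, 3, 4, 100), 0.25))
  expect_equal(b$q1, 2)
  expect_equal(b$q3, 4)
  expect_equal(b$lower, -1)
  expect_equal(b$upper, 7)
  expect_equal(b$upper - b$lower, 4 * b$iqr)

  const <- iqr_bounds(rep(7, 9))
  expect_equal(const$lower, 7)
  expect_equal(const$upper, 7)

  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1))
    b <- iqr_bounds(x)
    expect_equal(b$q1, oracle_quartile(x, 0.25))
    expect_equal(b$q3, oracle_quartile(x, 0.75))
    expect_true(b$lower <= b$q1 && b$q1 <= b$q3 && b$q3 <= b$upper)
  }
  expect_error(iqr_bounds(numeric(0)), "empty")
})

test_that("fence outliers are replaced by the pre-replacement median", {
  out <- impute_outliers_median(c(1, 2, 3, 4, 100))
  expect_equal(out$column, c(1, 2, 3, 4, 3))
  expect_equal(out$n_imputed, 1)

  clean <- impute_outliers_median(c(1, 2, 3, 4, 5))
  expect_equal(clean$n_imputed, 0)
  expect_equal(clean$column, c(1, 2, 3, 4, 5))

  const <- impute_outliers_median(rep(4, 6))
  expect_equal(const$n_imputed, 0)

  # n_imputed equals the out-of-bound count; in-bound values never change;
  # idempotent
  set.seed(8)
  for (i in 1:10) {
    x <- c(rnorm(40), rnorm(3, 20))
    b <- iqr_bounds(x)
    out <- impute_outliers_median(x)
    expect_equal(out$n_imputed, sum(x < b$lower | x > b$upper))
    inb <- x >= b$lower & x <= b$upper
    expect_equal(out$column[inb], x[inb])
    expect_true(all(out$column >= b$lower & out$column <= b$upper))
    # idempotent under the detection-time fences
    again <- impute_outliers_median(out$column, bounds = out$bounds)
    expect_equal(again$column, out$column)
    expect_equal(again$n_imputed, 0)
  }
})

test_that("robust scaling centres by median and divides by IQR", {
  tab <- make_small_table(30)
  tab$age <- seq_len(30)  # known quartiles
  sc <- robust_scale(tab, columns = "age")
  med <- median(1:30); iqr <- unname(diff(quantile(1:30, c(.25, .75))))
  expect_equal(sc$table$age, (1:30 - med) / iqr)
  # fit-subset median 0 and IQR 1 after scaling
  expect_equal(median(sc$table$age), 0, tolerance = 1e-9)
  expect_equal(unname(diff(quantile(sc$table$age, c(.25, .75)))), 1,
               tolerance = 1e-9)
  # worked example
  df <- data.frame(x = c(1, 2, 3, 4, 5))
  out <- robust_scale(df, columns = "x")
  expect_equal(out$table$x, c(-1, -0.5, 0, 0.5, 1))
})

test_that("degenerate (zero-IQR) columns pass through flagged and unscaled", {
  df <- data.frame(x = rep(3, 10), y = 1:10)
  out <- robust_scale(df, columns = c("x", "y"))
  expect_equal(out$table$x, rep(3, 10))
  expect_equal(out$params$degenerate, "x")
})

test_that("the target column is never scaled by the pipeline", {
  g <- generate_cohort(cohort_config(120, seed = 4))
  res <- run_pipeline(g$table)
  expect_true(all(res$table$target %in% c(0, 1)))
})

test_that("scale parameters frozen on a training subset transfer to new rows", {
  tab <- make_small_table(60)
  fit_rows <- 1:40
  sc <- robust_scale(tab, fit_rows = fit_rows)
  reapplied <- apply_scale(tab, sc$params)
  expect_equal(as.data.frame(reapplied), as.data.frame(sc$table))
})

test_that("pearson correlation matches its closed form and contracts", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_equal(pearson_correlation(x, c(1, 3, 2, 4)), 0.8)
  # symmetry + |r| <= 1 + positive-affine invariance on random input
  set.seed(21)
  for (i in 1:15) {
    a <- rnorm(20); b <- rnorm(20)
    r <- pearson_correlation(a, b)
    expect_equal(r, pearson_correlation(b, a))
    expect_lte(abs(r), 1)
    expect_equal(pearson_correlation(3 * a + 2, b), r)
  }
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_correlation(1:3, 1:4), "length")
})

test_that("pipeline on a clean table changes values only by scaling", {
  g <- generate_cohort(cohort_config(200, seed = 7))
  clean <- g$table
  # strip natural fence outliers (to a fixed point) so only scaling remains
  for (nm in schema_continuous()) {
    repeat {
      imp <- impute_outliers_median(clean[[nm]])
      clean[[nm]] <- imp$column
      if (imp$n_imputed == 0) break
    }
  }
  res <- run_pipeline(clean)
  expect_equal(res$log$missing_filled, 0)
  expect_equal(res$log$duplicates_removed, 0)
  expect_equal(sum(res$log$outliers_imputed), 0)
  expect_gt(length(res$log$columns_scaled), 0)
  expect_equal(nrow(res$table), nrow(clean))
})

test_that("pipeline output has no missing cells and no duplicate rows", {
  g <- generate_cohort(cohort_config(300, seed = 12))
  cc <- corrupt_cohort(g$table, corruption_plan(300, seed = 12))
  res <- run_pipeline(cc$table)
  expect_equal(sum(is.na(res$table)), 0)
  expect_equal(sum(duplicated(as.data.frame(res$table))), 0)
  # column set conserved
  expect_setequal(names(res$table), names(g$table))
})
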