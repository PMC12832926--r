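#' Forward-fill ("padding") imputation of missing cells
#'
#' Each missing cell is filled with the nearest preceding observed value in
#' its column. The method is undefined when a column's first row is missing,
#' so that case is an error naming the offending column.
#'
#' @param table a [cohort_table()] (or data.frame) possibly containing `NA`s
#' @return the table with zero missing cells; observed cells unchanged
#' @examples
#' df <- data.frame(x = c(3, NA, 5))
#' pad_interpolate(df)$x  # 3 3 5
#' @export
pad_interpolate <- function(table) {
  for (nm in names(table)) {
    col <- table[[nm]]
    if (anyNA(col)) {
      if (is.na(col[1L]))
        stop("column '", nm, "' starts with a missing value; ",
             "forward-fill imputation is undefined", call. = FALSE)
      table[[nm]] <- zoo::na.locf(col)
    }
  }
  table
}

#' Remove exact-duplicate rows
#'
#' Rows equal on every column are reduced to their first occurrence,
#' preserving the relative order of the kept rows. Intended to run after
#' [pad_interpolate()] (comparison is on raw, unscaled values).
#'
#' @param table a cohort table with no missing cells
#' @return list with `table` (deduplicated) and `removed_count`
#' @export
drop_duplicates <- function(table) {
  dup <- duplicated(as.data.frame(table))
  out <- table[!dup, , drop = FALSE]
  if (inherits(table, "cohort_table")) out <- keep_table(out, table)
  rownames(out) <- NULL
  list(table = out, removed_count = sum(dup))
}

#' Tukey fences from the interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). The fences are `Q1 - 1.5*IQR` and
#' `Q3 + 1.5*IQR`; values strictly outside them are treated as outliers.
#'
#' @param column numeric vector, no missing values
#' @return an `outlier_bounds` list: `q1`, `q3`, `iqr`, `lower`, `upper`
#' @examples
#' iqr_bounds(c(1, 2, 3, 4, 100))  # lower -1, upper 7
#' @export
iqr_bounds <- function(column) {
  if (length(column) == 0L) stop("empty column", call. = FALSE)
  if (anyNA(column)) stop("column contains missing values", call. = FALSE)
  q <- unname(stats::quantile(column, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr,
                 lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr),
            class = "outlier_bounds")
}

#' @export
print.outlier_bounds <- function(x, ...) {
  cat(sprintf("Q1 %.4g  Q3 %.4g  IQR %.4g  fences [%.4g, %.4g]\n",
              x$q1, x$q3, x$iqr, x$lower, x$upper))
  invisible(x)
}

#' Median imputation of fence outliers
#'
#' Values strictly outside the Tukey fences are replaced by the column
#' median; the median is that of the full input column, computed once before
#' any replacement. This is a single detect-and-replace pass: replacing
#' extremes shifts the quartiles slightly, so re-detecting on the output can
#' in principle flag new points. Re-running with the returned `bounds` is
#' the identity.
#'
#' @param column numeric vector, no missing values
#' @param bounds an [iqr_bounds()] object; defaults to the fences of
#'   `column` itself
#' @return list with `column` (imputed), `n_imputed`, and the `bounds` used
#' @examples
#' impute_outliers_median(c(1, 2, 3, 4, 100))$column  # 1 2 3 4 3
#' @export
impute_outliers_median <- function(column, bounds = NULL) {
  if (length(column) == 0L) stop("empty column", call. = FALSE)
  b <- if (is.null(bounds)) iqr_bounds(column) else bounds
  med <- stats::median(column)
  out <- column < b$lower | column > b$upper
  column[out] <- med
  list(column = column, n_imputed = sum(out), bounds = b)
}

#' Robust scaling by median and interquartile range
#'
#' Scaled value = (x - median) / IQR, with the median and IQR estimated on
#' the `fit_rows` subset only. Two fit modes are natural: fitting on the
#' whole table before any split (the protocol the composite-cohort study
#' uses) or fitting on training rows only and applying the frozen parameters
#' to held-out rows (leakage-safe; pass the training indices as `fit_rows`).
#' The target column is never scaled; columns with zero IQR on the fit subset
#' are passed through unchanged and flagged as degenerate.
#'
#' @param table a cohort table with no missing cells
#' @param fit_rows integer row indices on which to estimate median/IQR
#'   (default: all rows, the whole-table protocol)
#' @param columns columns to scale (default: every non-target column)
#' @return list with `table` (scaled) and `params`, a `scale_params` object
#'   holding per-column `median`, `iqr` and the `degenerate` column names
#' @export
robust_scale <- function(table, fit_rows = seq_len(nrow(table)),
                         columns = NULL) {
  if (length(fit_rows) == 0L) stop("fit subset is empty", call. = FALSE)
  sch <- table_schema(table)
  if (is.null(columns)) columns <- setdiff(names(table), sch$target)
  med <- iqr <- stats::setNames(numeric(length(columns)), columns)
  degenerate <- character(0)
  for (nm in columns) {
    fit <- table[[nm]][fit_rows]
    med[nm] <- stats::median(fit)
    iqr[nm] <- unname(diff(stats::quantile(fit, c(0.25, 0.75), type = 7)))
    if (iqr[nm] > 0) {
      table[[nm]] <- (table[[nm]] - med[nm]) / iqr[nm]
    } else {
      degenerate <- c(degenerate, nm)
    }
  }
  params <- structure(list(median = med, iqr = iqr, columns = columns,
                           degenerate = degenerate),
                      class = "scale_params")
  list(table = table, params = params)
}

#' Apply previously fitted robust-scale parameters to another table
#' @param table a cohort table
#' @param params a `scale_params` from [robust_scale()]
#' @return the scaled table
#' @export
apply_scale <- function(table, params) {
  for (nm in params$columns) {
    if (nm %in% params$degenerate) next
    table[[nm]] <- (table[[nm]] - params$median[nm]) / params$iqr[nm]
  }
  table
}

#' Pearson correlation between two feature vectors
#'
#' Thin, validating wrapper around the product-moment correlation: errors on
#' length mismatch or constant input rather than returning `NA`.
#'
#' @param x,y equal-length numeric vectors, each non-constant
#' @return correlation coefficient in \[-1, 1\]
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least two observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' The fixed data-refinement pipeline
#'
#' Applies, in order: forward-fill imputation of missing cells, exact
#' duplicate removal, fence-outlier median imputation on continuous columns,
#' and robust scaling. The order matters: duplicates are compared on raw
#' filled values, and outlier fences are computed on the deduplicated data.
#'
#' @param table a cohort table (may contain missing cells)
#' @param outlier_columns columns to fence (default: the schema's continuous
#'   columns)
#' @param scale_columns columns to robust-scale (default: all non-target)
#' @param scale_fit `"paper"` to fit scaling on all rows of the cleaned
#'   table, or `"safe"` with `fit_rows` supplied to fit on a training subset
#' @param fit_rows row indices (into the cleaned table) used when
#'   `scale_fit = "safe"`
#' @return list with `table` (cleaned and scaled) and `log`, a
#'   `pipeline_log` recording per-stage counts: `missing_filled`,
#'   `duplicates_removed`, `outliers_imputed` (per column), `columns_scaled`,
#'   `degenerate_columns`, and the per-column detection fences `bounds`
#' @export
run_pipeline <- function(table, outlier_columns = NULL, scale_columns = NULL,
                         scale_fit = c("paper", "safe"), fit_rows = NULL) {
  scale_fit <- match.arg(scale_fit)
  sch <- table_schema(table)
  if (is.null(outlier_columns))
    outlier_columns <- intersect(schema_continuous(sch), names(table))

  missing_filled <- sum(is.na(table))
  table <- pad_interpolate(table)

  dd <- drop_duplicates(table)
  table <- dd$table

  outliers <- stats::setNames(integer(length(outlier_columns)), outlier_columns)
  bounds <- list()
  for (nm in outlier_columns) {
    imp <- impute_outliers_median(table[[nm]])
    table[[nm]] <- imp$column
    outliers[nm] <- imp$n_imputed
    bounds[[nm]] <- imp$bounds
  }

  if (scale_fit == "safe") {
    if (is.null(fit_rows))
      stop("scale_fit = 'safe' requires fit_rows", call. = FALSE)
  } else {
    fit_rows <- seq_len(nrow(table))
  }
  sc <- robust_scale(table, fit_rows = fit_rows, columns = scale_columns)

  log <- structure(list(
    missing_filled = missing_filled,
    duplicates_removed = dd$removed_count,
    outliers_imputed = outliers,
    columns_scaled = setdiff(sc$params$columns, sc$params$degenerate),
    degenerate_columns = sc$params$degenerate,
    bounds = bounds,
    quartile_method = "type 7 (linear interpolation)",
    scale_fit = scale_fit
  ), class = "pipeline_log")

  list(table = sc$table, log = log, scale_params = sc$params)
}

#' @export
print.pipeline_log <- function(x, ...) {
  cat("Pipeline log\n")
  cat("  missing cells filled:   ", x$missing_filled, "\n")
  cat("  duplicate rows removed: ", x$duplicates_removed, "\n")
  cat("  outliers imputed:       ", sum(x$outliers_imputed),
      paste0("(", paste(names(x$outliers_imputed), x$outliers_imputed,
                        sep = "=", collapse = ", "), ")\n"))
  cat("  columns scaled:         ", length(x$columns_scaled), "\n")
  if (length(x$degenerate_columns))
    cat("  degenerate (unscaled):  ",
        paste(x$degenerate_columns, collapse = ", "), "\n")
  cat("  quartiles:              ", x$quartile_method, "\n")
  invisible(x)
}
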