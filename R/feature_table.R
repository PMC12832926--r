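#' Construct a cohort feature table
#'
#' A `cohort_table` is a plain `data.frame` carrying the schema as an
#' attribute. Missing cells are `NA`; categorical columns hold integer codes.
#' Every function in the package accepts and returns this shape, so standard
#' data-frame tooling keeps working.
#'
#' @param df a data.frame whose columns are exactly the schema's columns
#'   (order is normalised to the schema order)
#' @param schema a [heart_schema()]-style `cohort_schema`
#' @param validate check categorical codes and column presence (default TRUE)
#' @return `df`, reordered to schema order, classed `cohort_table`
#' @export
cohort_table <- function(df, schema = heart_schema(), validate = TRUE) {
  stopifnot(is.data.frame(df))
  if (validate) {
    missing_cols <- setdiff(schema$columns$name, names(df))
    if (length(missing_cols) > 0L)
      stop("missing schema column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    extra <- setdiff(names(df), schema$columns$name)
    if (length(extra) > 0L)
      stop("column(s) not in schema: ", paste(extra, collapse = ", "),
           call. = FALSE)
    if (nrow(df) < 1L) stop("cohort must have at least one row", call. = FALSE)
    for (nm in schema$columns$name) {
      codes <- schema_codes(schema, nm)
      if (!is.null(codes)) {
        vals <- df[[nm]][!is.na(df[[nm]])]
        bad <- setdiff(unique(vals), codes)
        if (length(bad) > 0L)
          stop("column '", nm, "' contains codes outside its schema set: ",
               paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  df <- df[, schema$columns$name, drop = FALSE]
  df <- as.data.frame(df)
  rownames(df) <- NULL
  attr(df, "schema") <- schema
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x), "patients x", ncol(x), "columns;",
      sum(is.na(x)), "missing cells\n")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Schema attached to a cohort table
#' @param table a `cohort_table` (falls back to [heart_schema()] for plain
#'   data frames)
#' @return the `cohort_schema`
#' @export
table_schema <- function(table) {
  sch <- attr(table, "schema")
  if (is.null(sch)) heart_schema() else sch
}

# keep class/schema through row subsetting done internally
keep_table <- function(df, template) {
  attr(df, "schema") <- table_schema(template)
  class(df) <- c("cohort_table", "data.frame")
  rownames(df) <- NULL
  df
}
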