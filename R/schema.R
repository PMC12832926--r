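#' The 14-attribute heart-disease cohort schema
#'
#' Describes the standard UCI-style heart-disease attribute set: column order,
#' kind (continuous, categorical, binary, target), the admissible value range
#' or code set, and the tokens that denote a missing cell in CSV files.
#'
#' Continuous attributes carry the physiologic ranges of the composite cohort
#' (age 28--77 years, resting blood pressure 80--200 mm Hg, cholesterol
#' 85--603 mg/dl, maximum heart rate 60--202 bpm, ST depression -2.6--6.2);
#' categorical attributes carry their integer code sets. `target` is coded
#' 1 = disease present, 0 = absent.
#'
#' @param missing_tokens character tokens mapped to a missing cell when
#'   reading CSV files. Defaults cover the UCI convention (`"?"`) plus empty
#'   and `"NA"` cells.
#' @return An object of class `cohort_schema`: a list with `columns`
#'   (a data.frame of name/kind/lower/upper/codes), `target` (the target
#'   column name) and `missing_tokens`.
#' @examples
#' sch <- heart_schema()
#' sch$columns$name
#' @export
heart_schema <- function(missing_tokens = c("?", "", "NA")) {
  col <- function(name, kind, lower = NA_real_, upper = NA_real_, codes = NULL) {
    list(name = name, kind = kind, lower = lower, upper = upper,
         codes = if (is.null(codes)) NA_character_ else paste(codes, collapse = ","))
  }
  cols <- list(
    col("age",      "continuous", 28, 77),
    col("sex",      "binary",      codes = 0:1),
    col("cp",       "categorical", codes = 0:3),
    col("trestbps", "continuous", 80, 200),
    col("chol",     "continuous", 85, 603),
    col("restecg",  "categorical", codes = 0:2),
    col("fbs",      "binary",      codes = 0:1),
    col("thalach",  "continuous", 60, 202),
    col("exang",    "binary",      codes = 0:1),
    col("oldpeak",  "continuous", -2.6, 6.2),
    col("slope",    "categorical", codes = 0:2),
    col("ca",       "categorical", codes = 0:3),
    col("thal",     "categorical", codes = 0:2),
    col("target",   "target",      codes = 0:1)
  )
  columns <- do.call(rbind, lapply(cols, function(x) {
    data.frame(name = x$name, kind = x$kind, lower = x$lower,
               upper = x$upper, codes = x$codes, stringsAsFactors = FALSE)
  }))
  structure(list(columns = columns, target = "target",
                 missing_tokens = missing_tokens),
            class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat("Cohort schema:", nrow(x$columns), "columns; target =", x$target, "\n")
  print(x$columns, row.names = FALSE)
  invisible(x)
}

#' Names of the schema's feature columns (everything except the target)
#' @param schema a `cohort_schema`
#' @return character vector of feature column names
#' @export
schema_features <- function(schema = heart_schema()) {
  setdiff(schema$columns$name, schema$target)
}

#' Names of the schema's continuous columns
#'
#' These are the columns on which interquartile-range outlier fencing is
#' meaningful; categorical/binary codes are excluded because quartile fences
#' on codes are not interpretable.
#' @param schema a `cohort_schema`
#' @return character vector of continuous column names
#' @export
schema_continuous <- function(schema = heart_schema()) {
  schema$columns$name[schema$columns$kind == "continuous"]
}

# range lookup for one schema column; categorical columns get code bounds
schema_range <- function(schema, name) {
  row <- schema$columns[schema$columns$name == name, , drop = FALSE]
  if (nrow(row) == 0L) stop("unknown schema column: ", name, call. = FALSE)
  if (!is.na(row$lower)) return(c(row$lower, row$upper))
  codes <- as.numeric(strsplit(row$codes, ",")[[1]])
  range(codes)
}

schema_codes <- function(schema, name) {
  row <- schema$columns[schema$columns$name == name, , drop = FALSE]
  if (is.na(row$codes)) return(NULL)
  as.numeric(strsplit(row$codes, ",")[[1]])
}
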