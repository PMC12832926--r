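#' Read a cohort CSV file
#'
#' Reads the 14-column cohort dialect: header row required, missing cells
#' encoded as `"?"`, `""` or `"NA"`. Tokens that neither parse as numbers
#' nor map to missing raise an error with row/column coordinates. Values
#' outside the schema's continuous ranges are admitted (they may be the
#' very outliers the pipeline exists to fix) but reported via a message.
#'
#' @param path CSV file path
#' @param schema a `cohort_schema`
#' @return a [cohort_table()]
#' @export
read_cohort_csv <- function(path, schema = heart_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(schema$columns$name, names(raw))
  if (length(missing_cols) > 0)
    stop("missing schema column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (nm in schema$columns$name) {
    tok <- trimws(raw[[nm]])
    is_missing <- tok %in% schema$missing_tokens
    val <- suppressWarnings(as.numeric(tok))
    bad <- which(!is_missing & is.na(val))
    if (length(bad) > 0)
      stop("unparseable token '", tok[bad[1]], "' at row ", bad[1],
           ", column '", nm, "'", call. = FALSE)
    val[is_missing] <- NA
    codes <- schema_codes(schema, nm)
    if (!is.null(codes)) {
      off <- which(!is.na(val) & !(val %in% codes))
      if (length(off) > 0)
        stop("code ", val[off[1]], " at row ", off[1], ", column '", nm,
             "' is outside the schema code set", call. = FALSE)
    } else {
      rng <- schema_range(schema, nm)
      n_out <- sum(!is.na(val) & (val < rng[1] | val > rng[2]))
      if (n_out > 0)
        message(n_out, " value(s) in column '", nm,
                "' outside the schema range [", rng[1], ", ", rng[2],
                "] (admitted; candidate outliers)")
    }
    out[[nm]] <- val
  }
  cohort_table(as.data.frame(out), schema = schema)
}

#' Write a cohort table as CSV
#'
#' Missing cells are written with the `"?"` token, so a write/read round
#' trip is the identity including missing markers.
#'
#' @param table a `cohort_table`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_cohort_csv <- function(table, path) {
  df <- as.data.frame(table)
  for (nm in names(df)) {
    v <- as.character(df[[nm]])
    v[is.na(df[[nm]])] <- "?"
    df[[nm]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

report_cell_list <- function(cell) {
  list(counts = unclass(cell$counts),
       panel = lapply(unclass(cell$panel), as.numeric),
       lr_plus = cell$ratios$lr_plus, lr_minus = cell$ratios$lr_minus,
       dor = cell$ratios$dor,
       selected_features = cell$spec$selected_features,
       hyperparams = cell$spec$hyperparams,
       family = cell$spec$family)
}

#' Serialise an experiment report
#'
#' JSON output is loss-free for counts, panels, likelihood ratios and chosen
#' model specifications, and can be read back with [read_report_json()].
#' Markdown output mirrors the canonical result-table layouts: one row per
#' family x ratio cell with the proportion metrics (balanced accuracy,
#' accuracy, sensitivity, specificity, precision, F1, NPV, MCC) as
#' percentages at two decimals (half-up), followed by an LR+/LR-/DOR table.
#'
#' @param report an `experiment_report`
#' @param path output file path
#' @param format `"json"` or `"markdown"`
#' @return `path`, invisibly
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(mode = report$plan$mode,
                    cells = lapply(report$cells, report_cell_list))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(path))
  }
  pct <- function(x) sprintf("%.2f", round_half_up(100 * as.numeric(x), 2))
  lines <- c(
    paste0("# Experiment report (", report$plan$mode, " mode)"), "",
    "| Model | Ratio | Balanced accuracy | Accuracy | Sensitivity | Specificity | Precision | F1 Score | NPV | MCC |",
    "|---|---|---|---|---|---|---|---|---|---|")
  for (nm in names(report$cells)) {
    p <- report$cells[[nm]]$panel
    parts <- strsplit(nm, "@", fixed = TRUE)[[1]]
    lines <- c(lines, paste0(
      "| ", parts[1], " | ", parts[2], " | ",
      paste(pct(p$balanced_accuracy), pct(p$accuracy), pct(p$sensitivity),
            pct(p$specificity), pct(p$precision), pct(p$f1), pct(p$npv),
            pct(p$mcc), sep = " | "), " |"))
  }
  lines <- c(lines, "", "| Model | Ratio | LR+ | LR- | DOR |", "|---|---|---|---|---|")
  for (nm in names(report$cells)) {
    r <- report$cells[[nm]]$ratios
    parts <- strsplit(nm, "@", fixed = TRUE)[[1]]
    lines <- c(lines, sprintf("| %s | %s | %.2f | %.4f | %.2f |",
                              parts[1], parts[2],
                              round_half_up(r$lr_plus, 2),
                              round_half_up(r$lr_minus, 4),
                              round_half_up(r$dor, 2)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a JSON experiment report
#' @param path a file written by [write_report()] with `format = "json"`
#' @return list with `mode` and `cells`
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
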