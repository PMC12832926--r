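#' Configuration for a synthetic clinical cohort
#'
#' The generator emulates the composite heart-disease cohort's schema and
#' marginals: continuous features are truncated normals centred mid-range
#' with sd = range/6, categorical codes are uniform except `sex` (0.76
#' male), and the 0/1 target follows a logistic model over the standardised
#' informative features with the stated log-odds effects, intercept
#' calibrated so the expected prevalence matches `prevalence` (52.86%
#' positive by default). Every feature not in `informative_features` is a
#' decoy with zero effect.
#'
#' @param n_patients cohort size
#' @param prevalence target-positive fraction (default 0.5286)
#' @param informative_features feature names with nonzero effect
#' @param effect_sizes named log-odds coefficients per standardised unit of
#'   each informative feature
#' @param noise_scale sd of residual logit noise (default 0.5)
#' @param male_fraction P(sex = 1) (default 0.76)
#' @param seed RNG seed
#' @param schema a `cohort_schema`
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_patients,
                          prevalence = 0.5286,
                          informative_features = c("cp", "oldpeak", "ca", "thal"),
                          effect_sizes = NULL,
                          noise_scale = 0.5,
                          male_fraction = 0.76,
                          seed = 1,
                          schema = heart_schema()) {
  stopifnot(n_patients >= 2, prevalence > 0, prevalence < 1)
  feats <- schema_features(schema)
  if (!all(informative_features %in% feats))
    stop("informative features must be schema features", call. = FALSE)
  if (is.null(effect_sizes))
    effect_sizes <- stats::setNames(rep(1.0, length(informative_features)),
                                    informative_features)
  if (!setequal(names(effect_sizes), informative_features))
    stop("effect_sizes must be named by the informative features", call. = FALSE)
  structure(list(n_patients = n_patients, prevalence = prevalence,
                 informative_features = informative_features,
                 effect_sizes = effect_sizes, noise_scale = noise_scale,
                 male_fraction = male_fraction, seed = seed, schema = schema),
            class = "cohort_config")
}

# truncated normal on [lo, hi], mid-range mean, sd = range/6
rtruncnorm_mid <- function(n, lo, hi) {
  m <- (lo + hi) / 2; s <- (hi - lo) / 6
  u <- stats::runif(n, stats::pnorm((lo - m) / s), stats::pnorm((hi - m) / s))
  m + s * stats::qnorm(u)
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param config a [cohort_config()]
#' @return list with `table` (a `cohort_table`) and `truth`: the informative
#'   feature set, their coefficients, the calibrated intercept, and the
#'   per-row linear predictor
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sch <- config$schema
  n <- config$n_patients
  with_seed(config$seed, {
    df <- list()
    for (i in seq_len(nrow(sch$columns))) {
      nm <- sch$columns$name[i]; kind <- sch$columns$kind[i]
      if (nm == sch$target) next
      if (kind == "continuous") {
        rng <- schema_range(sch, nm)
        x <- rtruncnorm_mid(n, rng[1], rng[2])
        # integer-typed vitals are recorded to the unit; ST depression to 0.1
        df[[nm]] <- if (nm == "oldpeak") round(x, 1) else round(x)
      } else if (nm == "sex") {
        df[[nm]] <- stats::rbinom(n, 1, config$male_fraction)
      } else {
        codes <- schema_codes(sch, nm)
        df[[nm]] <- sample(codes, n, replace = TRUE)
      }
    }
    lin <- numeric(n)
    for (nm in config$informative_features) {
      z <- (df[[nm]] - mean(df[[nm]])) / stats::sd(df[[nm]])
      lin <- lin + config$effect_sizes[[nm]] * z
    }
    if (config$noise_scale > 0)
      lin <- lin + stats::rnorm(n, 0, config$noise_scale)
    # calibrate the intercept so E[P(target = 1)] equals the prevalence
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lin)) - config$prevalence,
                         c(-20, 20))$root
    df[[sch$target]] <- stats::rbinom(n, 1, stats::plogis(b0 + lin))
    table <- cohort_table(as.data.frame(df), schema = sch)
    truth <- list(informative_features = config$informative_features,
                  effect_sizes = config$effect_sizes,
                  intercept = b0, linear_predictor = b0 + lin)
    list(table = table, truth = truth)
  })
}

# per-attribute missing tallies of the merged 1,190-patient cohort,
# mirrored proportionally onto cohorts of other sizes
.reference_missing_rates <- c(
  trestbps = 60, chol = 202, fbs = 90, restecg = 2, thalach = 55,
  exang = 55, oldpeak = 62, slope = 308, ca = 611, thal = 479
) / 1190

#' Plan for injecting data pathologies into a cohort
#'
#' @param n_patients size of the cohort the plan targets
#' @param missing_counts named integer vector of cells to blank per feature;
#'   defaults mirror the merged reference cohort's per-attribute missingness
#'   proportions
#' @param duplicate_fraction fraction of rows to duplicate (default 0.2269)
#' @param outlier_fraction fraction of rows per continuous column receiving
#'   an injected outlier (default 0.02)
#' @param outlier_multiplier injected values sit this many IQRs beyond the
#'   Tukey fence (default 3), so detection is unambiguous
#' @param seed RNG seed
#' @return a `corruption_plan` list
#' @export
corruption_plan <- function(n_patients,
                            missing_counts = NULL,
                            duplicate_fraction = 0.2269,
                            outlier_fraction = 0.02,
                            outlier_multiplier = 3,
                            seed = 1) {
  if (is.null(missing_counts))
    missing_counts <- round(.reference_missing_rates * n_patients)
  missing_counts <- missing_counts[missing_counts > 0]
  stopifnot(duplicate_fraction >= 0, outlier_fraction >= 0,
            outlier_multiplier > 0)
  structure(list(n_patients = n_patients,
                 missing_counts = missing_counts,
                 duplicate_fraction = duplicate_fraction,
                 outlier_fraction = outlier_fraction,
                 outlier_multiplier = outlier_multiplier, seed = seed),
            class = "corruption_plan")
}

#' Inject missing cells, duplicate rows and fence outliers into a cohort
#'
#' Duplicated rows are inserted at random positions (never displacing row 1);
#' cell-level corruptions (blanking, outlier injection) touch only rows not
#' involved in a duplicate pair and never row 1, so that the cleaning
#' pipeline's stage counts are exactly predictable from the returned ledger.
#' Injected outliers are written as `fence +/- multiplier * IQR` excursions
#' of the pre-injection column.
#'
#' @param table a clean `cohort_table`
#' @param plan a [corruption_plan()]
#' @return list with `table` (corrupted) and `ledger` recording every
#'   altered cell: `missing` (row/column), `duplicates` (source ids, count),
#'   `outliers` (row/column/value)
#' @export
corrupt_cohort <- function(table, plan) {
  stopifnot(inherits(plan, "corruption_plan"))
  if (nrow(table) != plan$n_patients)
    stop("plan targets ", plan$n_patients, " rows, table has ", nrow(table),
         call. = FALSE)
  sch <- table_schema(table)
  with_seed(plan$seed, {
    n0 <- nrow(table)
    n_dup <- round(plan$duplicate_fraction * n0)
    src <- if (n_dup > 0) sort(sample(n0, n_dup)) else integer(0)

    # interleave the copies at random positions after row 1
    base <- as.data.frame(table)
    copies <- base[src, , drop = FALSE]
    all_rows <- rbind(base, copies)
    is_dup_involved <- c(seq_len(n0) %in% src, rep(TRUE, n_dup))
    ord <- c(1L, 1L + sample(nrow(all_rows) - 1L))
    all_rows <- all_rows[ord, , drop = FALSE]
    dup_involved <- is_dup_involved[ord]
    n <- nrow(all_rows)
    eligible <- setdiff(which(!dup_involved), 1L)

    # outlier injection on continuous columns, from pre-injection fences
    outlier_ledger <- list()
    cont <- intersect(schema_continuous(sch), names(all_rows))
    used <- lapply(stats::setNames(nm = names(all_rows)), function(x) integer(0))
    if (plan$outlier_fraction > 0) {
      for (nm in cont) {
        k <- round(plan$outlier_fraction * n0)
        if (k == 0) next
        if (k > length(eligible))
          stop("outlier plan infeasible for column ", nm, call. = FALSE)
        rows <- sample(eligible, k)
        b <- iqr_bounds(all_rows[[nm]])
        side <- sample(c(-1, 1), k, replace = TRUE)
        val <- ifelse(side > 0,
                      b$upper + plan$outlier_multiplier * max(b$iqr, 1),
                      b$lower - plan$outlier_multiplier * max(b$iqr, 1))
        if (nm != "oldpeak") val <- round(val)
        all_rows[[nm]][rows] <- val
        used[[nm]] <- rows
        outlier_ledger[[nm]] <- data.frame(row = rows, column = nm, value = val)
      }
    }

    # blanking: never row 1, never a duplicate-involved row, never an
    # injected-outlier cell of the same column
    missing_ledger <- list()
    for (nm in names(plan$missing_counts)) {
      k <- plan$missing_counts[[nm]]
      pool <- setdiff(eligible, used[[nm]])
      if (k > length(pool))
        stop("missing plan infeasible for column ", nm, call. = FALSE)
      rows <- sample(pool, k)
      all_rows[[nm]][rows] <- NA
      missing_ledger[[nm]] <- data.frame(row = rows, column = nm)
    }

    ledger <- list(
      missing = if (length(missing_ledger)) do.call(rbind, missing_ledger)
                else data.frame(row = integer(0), column = character(0)),
      n_missing = sum(unlist(plan$missing_counts)),
      duplicates = list(source_rows = src, count = n_dup),
      outliers = if (length(outlier_ledger)) do.call(rbind, outlier_ledger)
                 else data.frame(row = integer(0), column = character(0),
                                 value = numeric(0))
    )
    rownames(ledger$missing) <- rownames(ledger$outliers) <- NULL
    list(table = keep_table(all_rows, table), ledger = ledger)
  })
}
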