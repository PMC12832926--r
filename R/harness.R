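#' Plan for a split-grid experiment
#'
#' @param ratios train:test ratios as `"train:test"` strings; the canonical
#'   grid is 70:30, 80:20, 90:10
#' @param families classifier families to run
#' @param mode `"default"` (untuned baselines), `"standard-pso"` or
#'   `"ipso"`
#' @param split_seed split seed ("zero random states" convention: 0)
#' @param repeats number of repeated splits for statistical testing
#' @return an `experiment_plan` list
#' @export
experiment_plan <- function(ratios = c("70:30", "80:20", "90:10"),
                            families = c("lr", "lda", "gnb", "svc", "xgb"),
                            mode = c("default", "standard-pso", "ipso"),
                            split_seed = 0, repeats = 10) {
  mode <- match.arg(mode)
  stopifnot(repeats >= 1)
  structure(list(ratios = ratios, families = families, mode = mode,
                 split_seed = split_seed, repeats = repeats),
            class = "experiment_plan")
}

# evaluate a fitted model on held-out rows -> one report cell
evaluate_cell <- function(model, test, sch) {
  pred <- stats::predict(model, test, type = "label")
  counts <- tally_confusion(test[[sch$target]], pred)
  list(counts = counts,
       panel = metric_panel(counts, zero_division = "zero"),
       ratios = likelihood_ratios(counts, haldane = FALSE))
}

#' Run the default-model split grid
#'
#' For every family x ratio cell: stratified split at the plan's seed, fit
#' the family's default specification on all features, evaluate the held-out
#' metric panel and likelihood ratios.
#'
#' @param table a preprocessed cohort table
#' @param plan an [experiment_plan()] with `mode = "default"`
#' @return an `experiment_report`: list of cells keyed `family@ratio`, each
#'   with `counts`, `panel`, `ratios`, `spec`, and the split row ids
#' @export
run_default_grid <- function(table, plan = experiment_plan()) {
  if (plan$mode != "default")
    stop("plan mode must be 'default'", call. = FALSE)
  sch <- table_schema(table)
  feats <- intersect(schema_features(sch), names(table))
  cells <- list()
  for (ratio in plan$ratios) {
    split <- stratified_split(table[[sch$target]],
                              ratio_test_fraction(ratio), plan$split_seed)
    train <- keep_table(table[split$train, , drop = FALSE], table)
    test <- keep_table(table[split$test, , drop = FALSE], table)
    for (family in plan$families) {
      spec <- default_spec(family, feats)
      model <- fit_final(spec, train, seed = plan$split_seed)
      cell <- evaluate_cell(model, test, sch)
      cell$spec <- spec
      cell$split <- split
      cells[[paste0(family, "@", ratio)]] <- cell
    }
  }
  structure(list(cells = cells, plan = plan), class = "experiment_report")
}

#' Run the optimised-model split grid
#'
#' Per family x ratio cell: the swarm searches the joint feature-mask +
#' hyperparameter space, with cross-validated F1 computed on the training
#' portion only; the best specification is refit on the full training
#' portion and evaluated on the untouched test rows. A leakage audit
#' (disjointness of train/test row ids, and the guarantee that the fitness
#' closure only ever saw training rows) is stored per cell.
#'
#' @param table a preprocessed cohort table
#' @param plan an [experiment_plan()] with mode `"standard-pso"` or
#'   `"ipso"`
#' @param swarm a [swarm_config()]; for `"standard-pso"` mode it is
#'   degenerated to fixed inertia and no mutation
#' @param protocol a [fitness_protocol()]
#' @return an `experiment_report` whose cells also carry the chosen `spec`,
#'   the convergence `history` and a `leakage_audit`
#' @export
run_optimized_grid <- function(table, plan, swarm = swarm_config(),
                               protocol = fitness_protocol()) {
  if (!plan$mode %in% c("standard-pso", "ipso"))
    stop("plan mode must be 'standard-pso' or 'ipso'", call. = FALSE)
  if (plan$mode == "standard-pso")
    swarm <- standard_pso_config(n_particles = swarm$n_particles,
                                 max_iterations = swarm$max_iterations,
                                 c1 = swarm$c1, c2 = swarm$c2,
                                 v_max_fraction = swarm$v_max_fraction,
                                 seed = swarm$seed)
  sch <- table_schema(table)
  cells <- list()
  for (ratio in plan$ratios) {
    split <- stratified_split(table[[sch$target]],
                              ratio_test_fraction(ratio), plan$split_seed)
    train <- keep_table(table[split$train, , drop = FALSE], table)
    test <- keep_table(table[split$test, , drop = FALSE], table)
    for (family in plan$families) {
      tuned <- tune_model(family, train, config = swarm, protocol = protocol)
      model <- fit_final(tuned$spec, train, seed = protocol$eval_seed)
      cell <- evaluate_cell(model, test, sch)
      cell$spec <- tuned$spec
      cell$history <- tuned$state$history
      cell$cv_fitness <- tuned$fitness
      cell$split <- split
      cell$leakage_audit <- list(
        disjoint = length(intersect(split$train, split$test)) == 0,
        fitness_rows = split$train)
      cells[[paste0(family, "@", ratio)]] <- cell
    }
  }
  structure(list(cells = cells, plan = plan), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report (", x$plan$mode, " mode): ",
      length(x$cells), " cells\n", sep = "")
  for (nm in names(x$cells)) {
    p <- x$cells[[nm]]$panel
    cat(sprintf("  %-12s acc %5.2f%%  F1 %5.2f%%  DOR %s\n", nm,
                round_half_up(100 * p$accuracy, 2),
                round_half_up(100 * as.numeric(p$f1), 2),
                format(round_half_up(x$cells[[nm]]$ratios$dor, 2))))
  }
  invisible(x)
}

# arm A/C preprocessing: mean imputation + z-score standardisation
basic_preprocess <- function(table) {
  sch <- table_schema(table)
  for (nm in setdiff(names(table), sch$target)) {
    col <- table[[nm]]
    if (anyNA(col)) col[is.na(col)] <- mean(col, na.rm = TRUE)
    s <- stats::sd(col)
    table[[nm]] <- if (s > 0) (col - mean(col)) / s else col
  }
  if (anyNA(table[[sch$target]]))
    stop("target column may not contain missing values", call. = FALSE)
  table
}

#' Component ablation at a 90:10 split
#'
#' Four arms, XGBoost throughout: A = basic preprocessing (mean imputation +
#' z-score standardisation) with the default model; B = the full refinement
#' pipeline with the default model; C = basic preprocessing with
#' standard-PSO tuning; D = the full pipeline with IPSO tuning.
#'
#' @param raw_table a raw (possibly corrupted) cohort table
#' @param swarm a [swarm_config()] used for arms C (degenerated) and D
#' @param protocol a [fitness_protocol()]
#' @param split_seed split seed (default 0)
#' @param family classifier family for every arm (default `"xgb"`)
#' @return a data.frame with one row per arm (A--D): accuracy, F1, DOR
#' @export
run_ablation <- function(raw_table, swarm = swarm_config(),
                         protocol = fitness_protocol(),
                         split_seed = 0, family = "xgb") {
  sch <- table_schema(raw_table)
  basic <- basic_preprocess(raw_table)
  full <- run_pipeline(raw_table)$table
  arm <- function(table, mode) {
    plan <- experiment_plan(ratios = "90:10", families = family,
                            mode = mode, split_seed = split_seed)
    rep <- if (mode == "default") run_default_grid(table, plan)
           else run_optimized_grid(table, plan, swarm, protocol)
    cell <- rep$cells[[1]]
    data.frame(accuracy = 100 * cell$panel$accuracy,
               f1 = 100 * as.numeric(cell$panel$f1),
               dor = cell$ratios$dor)
  }
  out <- rbind(arm(basic, "default"),
               arm(full, "default"),
               arm(basic, "standard-pso"),
               arm(full, "ipso"))
  out <- cbind(configuration = c("A", "B", "C", "D"),
               description = c("basic preprocessing + default model",
                               "refinement pipeline + default model",
                               "basic preprocessing + standard PSO",
                               "refinement pipeline + IPSO"),
               out)
  rownames(out) <- NULL
  out
}

#' Two-sided paired t-test
#'
#' Thin validating wrapper over the paired t-test: errors on degenerate
#' (zero-variance) differences instead of returning `NaN`.
#'
#' @param scores_a,scores_b equal-length numeric vectors (>= 2) of paired
#'   scores, e.g. per-split accuracies of two models
#' @return list with `t`, `p`, `df`, `mean_difference` (a - b)
#' @export
paired_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(scores_a) < 2) stop("need at least two pairs", call. = FALSE)
  d <- scores_a - scores_b
  if (stats::sd(d) == 0)
    stop("degenerate variance: all paired differences identical", call. = FALSE)
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_difference = mean(d))
}

#' Feature selection frequency across optimisation runs
#'
#' @param runs list of `model_spec`s from repeated tuning runs
#' @param feature_labels the full candidate feature set (default: union of
#'   features appearing in any run)
#' @return named numeric vector: fraction of runs selecting each feature,
#'   sorted decreasing
#' @export
selection_frequency <- function(runs, feature_labels = NULL) {
  if (length(runs) == 0) stop("runs must be non-empty", call. = FALSE)
  if (is.null(feature_labels))
    feature_labels <- unique(unlist(lapply(runs, `[[`, "selected_features")))
  freq <- vapply(feature_labels, function(f)
    mean(vapply(runs, function(r) f %in% r$selected_features, logical(1))),
    numeric(1))
  sort(freq, decreasing = TRUE)
}
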