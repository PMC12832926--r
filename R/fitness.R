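#' Cross-validated fitness protocol
#'
#' The optimizer's objective: mean positive-class F1 over stratified k-fold
#' cross-validation, computed per fold then averaged. Folds are derived
#' deterministically from `eval_seed`, so the fitness is a pure function of
#' the decoded model specification.
#'
#' @param k_folds number of stratified folds (>= 2; default 5)
#' @param eval_seed seed controlling fold assignment and learner RNGs
#' @return a `fitness_protocol` list
#' @export
fitness_protocol <- function(k_folds = 5, eval_seed = 0) {
  stopifnot(k_folds >= 2)
  structure(list(k_folds = k_folds, eval_seed = eval_seed),
            class = "fitness_protocol")
}

fold_f1 <- function(y_true, y_pred) {
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  if (2 * tp + fp + fn == 0) return(0)   # zero-division-to-zero convention
  2 * tp / (2 * tp + fp + fn)
}

#' Cross-validated F1 of a model specification
#'
#' @param spec a [model_spec()]
#' @param table a preprocessed cohort table (training portion only, when
#'   called inside an optimisation: held-out rows must not reach this
#'   function)
#' @param protocol a [fitness_protocol()]
#' @return mean positive-class F1 across folds
#' @export
cv_fitness <- function(spec, table, protocol = fitness_protocol()) {
  sch <- table_schema(table)
  y <- table[[sch$target]]
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  fold <- stratified_folds(y, protocol$k_folds, protocol$eval_seed)
  f1 <- numeric(protocol$k_folds)
  for (k in seq_len(protocol$k_folds)) {
    train <- table[fold != k, , drop = FALSE]
    test <- table[fold == k, , drop = FALSE]
    train <- keep_table(train, table); test <- keep_table(test, table)
    model <- fit_final(spec, train, seed = protocol$eval_seed)
    pred <- stats::predict(model, test, type = "label")
    f1[k] <- fold_f1(test[[sch$target]], pred)
  }
  mean(f1)
}

# memoising fitness closure for the optimizer: identical decoded specs
# (common after integer rounding / mask thresholding) are evaluated once
make_cv_fitness <- function(space, table, protocol = fitness_protocol()) {
  cache <- new.env(parent = emptyenv())
  function(position) {
    spec <- decode_particle(position, space)
    key <- paste(c(sort(spec$selected_features),
                   signif(unlist(spec$hyperparams), 10)), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- cv_fitness(spec, table, protocol)
    cache[[key]] <- f
    f
  }
}

#' Jointly optimise features and hyperparameters for one family
#'
#' Runs the improved particle swarm over the family's joint mask +
#' hyperparameter space with cross-validated F1 as the objective, then
#' decodes the best particle.
#'
#' @param family classifier family label (see [build_space()])
#' @param table the training cohort table (preprocessed)
#' @param config a [swarm_config()]
#' @param protocol a [fitness_protocol()]
#' @param feature_labels candidate features (default: all schema features
#'   present in the table)
#' @return list with `spec` (the best decoded `model_spec`), `state` (the
#'   `swarm_state`), and `fitness` (its cross-validated F1)
#' @export
tune_model <- function(family, table, config = swarm_config(),
                       protocol = fitness_protocol(),
                       feature_labels = NULL) {
  sch <- table_schema(table)
  if (is.null(feature_labels))
    feature_labels <- intersect(schema_features(sch), names(table))
  space <- build_space(family, feature_labels)
  fitness <- make_cv_fitness(space, table, protocol)
  state <- ipso_optimize(space$n_dims, fitness, config)
  spec <- decode_particle(state$gbest_position, space)
  list(spec = spec, state = state, fitness = state$gbest_fitness)
}
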