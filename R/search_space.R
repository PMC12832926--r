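#' Joint feature-mask + hyperparameter search space for a classifier family
#'
#' The space has one binary-like mask dimension per candidate feature plus
#' the family's hyperparameter dimensions. Particles live in normalised
#' `[0,1]` coordinates; decoding to native ranges is [decode_particle()]'s
#' job. The hyperparameter ranges are versioned package constants:
#' \describe{
#'   \item{lr}{inverse regularisation strength `C` on log10 \[1e-3, 1e3\]
#'     (ridge-penalised logistic regression)}
#'   \item{lda}{pooled-covariance shrinkage in \[0, 1\]}
#'   \item{gnb}{variance-smoothing exponent in \[-12, -3\] (smoothing =
#'     `10^exponent` times the largest feature variance)}
#'   \item{svc}{RBF cost `C` and kernel width `gamma`, both log10
#'     \[1e-3, 1e3\]}
#'   \item{xgb}{`nrounds` in \[50, 500\], `max_depth` in \[2, 10\], `eta`
#'     log10 \[1e-3, 0.5\], `subsample` and `colsample_bytree` in
#'     \[0.5, 1\]}
#' }
#'
#' @param family one of `"lr"`, `"lda"`, `"gnb"`, `"svc"`, `"xgb"`
#' @param feature_labels candidate feature names (one mask dimension each)
#' @return a `search_space` list with `family`, `feature_labels`, `dims`
#'   (a data.frame of name/kind/lower/upper) and `n_dims`
#' @export
build_space <- function(family, feature_labels) {
  family <- match.arg(family, c("lr", "lda", "gnb", "svc", "xgb"))
  stopifnot(length(feature_labels) >= 1)
  dim_row <- function(name, kind, lower, upper)
    data.frame(name = name, kind = kind, lower = lower, upper = upper,
               stringsAsFactors = FALSE)
  hyper <- switch(family,
    lr  = dim_row("C", "log", -3, 3),
    lda = dim_row("shrinkage", "continuous", 0, 1),
    gnb = dim_row("var_smoothing_exp", "continuous", -12, -3),
    svc = rbind(dim_row("cost", "log", -3, 3),
                dim_row("gamma", "log", -3, 3)),
    xgb = rbind(dim_row("nrounds", "integer", 50, 500),
                dim_row("max_depth", "integer", 2, 10),
                dim_row("eta", "log", -3, log10(0.5)),
                dim_row("subsample", "continuous", 0.5, 1),
                dim_row("colsample_bytree", "continuous", 0.5, 1))
  )
  mask <- do.call(rbind, lapply(feature_labels, function(f)
    dim_row(paste0("mask_", f), "mask", 0, 1)))
  dims <- rbind(mask, hyper)
  structure(list(family = family, feature_labels = feature_labels,
                 dims = dims, n_dims = nrow(dims)),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat("Search space for family '", x$family, "': ",
      length(x$feature_labels), " mask dims + ",
      x$n_dims - length(x$feature_labels), " hyperparameter dims\n", sep = "")
  invisible(x)
}

#' Decode a normalised particle position into a model specification
#'
#' Mask dimensions at or above 0.5 select the feature; an all-empty mask is
#' repaired by selecting the single highest-valued mask dimension. Continuous
#' dimensions map affinely onto their range, log dimensions affinely in
#' log10 space, and integer dimensions are rounded half-up after the affine
#' map.
#'
#' @param position numeric vector in `[0,1]`, length `space$n_dims`
#' @param space a [build_space()] result
#' @return a `model_spec`: `family`, `selected_features`, `hyperparams`
#' @export
decode_particle <- function(position, space) {
  if (length(position) != space$n_dims)
    stop("position length ", length(position), " != space dimension ",
         space$n_dims, call. = FALSE)
  n_mask <- length(space$feature_labels)
  mask_vals <- position[seq_len(n_mask)]
  selected <- mask_vals >= 0.5
  if (!any(selected)) selected[which.max(mask_vals)] <- TRUE
  hyper_dims <- space$dims[-seq_len(n_mask), , drop = FALSE]
  hyper <- list()
  for (j in seq_len(nrow(hyper_dims))) {
    d <- hyper_dims[j, ]
    u <- position[n_mask + j]
    val <- switch(d$kind,
      continuous = d$lower + u * (d$upper - d$lower),
      log = 10^(d$lower + u * (d$upper - d$lower)),
      integer = round_half_up(d$lower + u * (d$upper - d$lower)),
      stop("unknown dimension kind: ", d$kind, call. = FALSE))
    hyper[[d$name]] <- val
  }
  model_spec(space$family, space$feature_labels[selected], hyper)
}

#' Construct a model specification
#' @param family classifier family label
#' @param selected_features non-empty character vector of feature names
#' @param hyperparams named list of hyperparameter values
#' @return a `model_spec`
#' @export
model_spec <- function(family, selected_features, hyperparams = list()) {
  if (length(selected_features) == 0L)
    stop("selected_features must be non-empty", call. = FALSE)
  structure(list(family = family,
                 selected_features = as.character(selected_features),
                 hyperparams = hyperparams),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec [", x$family, "]\n  features: ",
      paste(x$selected_features, collapse = ", "), "\n", sep = "")
  if (length(x$hyperparams))
    cat("  hyperparams:",
        paste(names(x$hyperparams), signif(unlist(x$hyperparams), 4),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Default (untuned) model specification for a family
#'
#' The baseline configurations of the split-grid experiment: all features,
#' the family's conventional defaults (`C = 1`, no LDA shrinkage, variance
#' smoothing `1e-9`, SVC `cost = 1` with `gamma = 1/p`, XGBoost 100 rounds
#' at depth 6 and `eta` 0.3).
#'
#' @param family classifier family label
#' @param feature_labels features to include (all, for the baseline)
#' @return a `model_spec`
#' @export
default_spec <- function(family, feature_labels) {
  family <- match.arg(family, c("lr", "lda", "gnb", "svc", "xgb"))
  hyper <- switch(family,
    lr  = list(C = 1),
    lda = list(shrinkage = 0),
    gnb = list(var_smoothing_exp = -9),
    svc = list(cost = 1, gamma = 1 / length(feature_labels)),
    xgb = list(nrounds = 100, max_depth = 6, eta = 0.3,
               subsample = 1, colsample_bytree = 1))
  model_spec(family, feature_labels, hyper)
}
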