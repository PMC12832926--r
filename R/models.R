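# Classifier family fits. Each family delegates to its established
# implementation; this file only adapts interfaces (feature masks, seeds,
# score extraction). The one hand-written fit is the shrinkage LDA, since
# the pooled-covariance shrinkage dimension of the search space has no
# direct counterpart in MASS::lda.

fit_lr <- function(X, y, hyper) {
  C <- hyper$C %||% 1
  n <- nrow(X)
  if (ncol(X) >= 2) {
    fit <- glmnet::glmnet(as.matrix(X), factor(y, levels = c(0, 1)),
                          family = "binomial", alpha = 0,
                          lambda = 1 / (C * n), standardize = FALSE)
    list(kind = "glmnet", fit = fit)
  } else {
    # glmnet needs >= 2 predictors; single-feature masks fall back to
    # unpenalised logistic regression
    df <- data.frame(y = y, X)
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    list(kind = "glm", fit = fit)
  }
}

predict_lr <- function(model, X) {
  if (model$kind == "glmnet")
    as.numeric(stats::predict(model$fit, as.matrix(X), type = "response"))
  else
    as.numeric(stats::predict(model$fit, newdata = as.data.frame(X),
                              type = "response"))
}

# Gaussian LDA with pooled covariance shrunk toward its average-diagonal:
# Sigma(a) = (1-a) * S_pooled + a * mean(diag(S_pooled)) * I
fit_lda <- function(X, y, hyper) {
  a <- hyper$shrinkage %||% 0
  X <- as.matrix(X)
  X0 <- X[y == 0, , drop = FALSE]; X1 <- X[y == 1, , drop = FALSE]
  n0 <- nrow(X0); n1 <- nrow(X1)
  if (n0 < 2 || n1 < 2) stop("need >= 2 rows per class", call. = FALSE)
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  S <- ((n0 - 1) * stats::cov(X0) + (n1 - 1) * stats::cov(X1)) / (n0 + n1 - 2)
  S <- (1 - a) * S + a * mean(diag(S)) * diag(ncol(X))
  W <- tryCatch(solve(S), error = function(e)
    solve(S + 1e-8 * mean(diag(S)) * diag(ncol(X))))
  list(W = W, mu0 = mu0, mu1 = mu1,
       log_prior0 = log(n0 / (n0 + n1)), log_prior1 = log(n1 / (n0 + n1)))
}

predict_lda <- function(model, X) {
  X <- as.matrix(X)
  d1 <- X %*% (model$W %*% model$mu1) -
    0.5 * drop(t(model$mu1) %*% model$W %*% model$mu1) + model$log_prior1
  d0 <- X %*% (model$W %*% model$mu0) -
    0.5 * drop(t(model$mu0) %*% model$W %*% model$mu0) + model$log_prior0
  stats::plogis(as.numeric(d1 - d0))
}

fit_gnb <- function(X, y, hyper) {
  vse <- hyper$var_smoothing_exp %||% -9
  fit <- e1071::naiveBayes(as.data.frame(X), factor(y, levels = c(0, 1)))
  # variance smoothing: add a fraction of the largest feature variance to
  # every class-conditional variance (stabilises near-constant features)
  eps <- 10^vse * max(vapply(as.data.frame(X), stats::var, numeric(1)))
  fit$tables <- lapply(fit$tables, function(tab) {
    tab[, 2] <- sqrt(tab[, 2]^2 + eps)
    tab
  })
  fit
}

predict_gnb <- function(model, X) {
  raw <- stats::predict(model, as.data.frame(X), type = "raw")
  as.numeric(raw[, "1"])
}

fit_svc <- function(X, y, hyper) {
  e1071::svm(as.matrix(X), factor(y, levels = c(0, 1)),
             kernel = "radial", cost = hyper$cost %||% 1,
             gamma = hyper$gamma %||% (1 / ncol(X)), scale = FALSE)
}

predict_svc <- function(model, X) {
  p <- stats::predict(model, as.matrix(X), decision.values = TRUE)
  dv <- attr(p, "decision.values")
  # orient the decision value so larger = class "1"
  score <- if (startsWith(colnames(dv)[1], "1/")) dv[, 1] else -dv[, 1]
  as.numeric(score)
}

fit_xgb <- function(X, y, hyper, seed) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  params <- list(objective = "binary:logistic",
                 max_depth = hyper$max_depth %||% 6,
                 eta = hyper$eta %||% 0.3,
                 subsample = hyper$subsample %||% 1,
                 colsample_bytree = hyper$colsample_bytree %||% 1,
                 nthread = 1, seed = seed)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = hyper$nrounds %||% 100, verbose = 0)
}

predict_xgb <- function(model, X) {
  as.numeric(stats::predict(model, xgboost::xgb.DMatrix(as.matrix(X))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a classifier from a model specification
#'
#' Fits the underlying learner on the spec's selected features only. The
#' returned predictor exposes hard labels and continuous scores (class-1
#' probability, or the decision value for the SVC) via
#' [predict.cardio_model()].
#'
#' @param spec a [model_spec()] / [decode_particle()] result
#' @param train a preprocessed cohort table with a 0/1 target column
#' @param seed seed forwarded to stochastic learners (XGBoost)
#' @return a fitted `cardio_model`
#' @export
fit_final <- function(spec, train, seed = 0) {
  sch <- table_schema(train)
  y <- train[[sch$target]]
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("training data must contain >= 2 rows of each class", call. = FALSE)
  X <- as.data.frame(train)[, spec$selected_features, drop = FALSE]
  fit <- switch(spec$family,
    lr  = fit_lr(X, y, spec$hyperparams),
    lda = fit_lda(X, y, spec$hyperparams),
    gnb = fit_gnb(X, y, spec$hyperparams),
    svc = fit_svc(X, y, spec$hyperparams),
    xgb = fit_xgb(X, y, spec$hyperparams, seed),
    stop("unknown family: ", spec$family, call. = FALSE))
  structure(list(spec = spec, fit = fit), class = "cardio_model")
}

#' Predict from a fitted cardio model
#' @param object a `cardio_model` from [fit_final()]
#' @param newdata a cohort table or data.frame holding the selected features
#' @param type `"label"` for hard 0/1 calls, `"score"` for continuous scores
#' @param ... unused
#' @return numeric vector of labels or scores
#' @export
predict.cardio_model <- function(object, newdata, type = c("label", "score"), ...) {
  type <- match.arg(type)
  X <- as.data.frame(newdata)[, object$spec$selected_features, drop = FALSE]
  score <- switch(object$spec$family,
    lr  = predict_lr(object$fit, X),
    lda = predict_lda(object$fit, X),
    gnb = predict_gnb(object$fit, X),
    svc = predict_svc(object$fit, X),
    xgb = predict_xgb(object$fit, X))
  if (type == "score") return(score)
  threshold <- if (object$spec$family == "svc") 0 else 0.5
  as.integer(score >= threshold)
}
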