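# R interface to the compiled gradient-boosted tree learner.
#
# The model mirrors the xgboost binary classifier the study used:
# second-order boosting on the logistic loss, per-tree row subsampling
# (without replacement) and column subsampling, gamma as the minimum loss
# reduction for a split, min_child_weight as the minimum child hessian sum,
# L2 leaf penalty lambda = 1, learning rate eta = 0.3, initial margin 0
# (base probability 0.5).  All sampling is drawn from R's RNG under `seed`,
# so a fit is fully reproducible.

#' Default gradient-boosting hyperparameters
#'
#' The tunable six (searched over the published grid) plus the fixed
#' learning rate and L2 penalty.
#' @return named list of hyperparameters.
#' @export
gbt_default_params <- function() {
  list(gamma = 0.6, colsample_bytree = 1, max_depth = 3,
       min_child_weight = 2, n_estimators = 100, subsample = 1,
       eta = 0.3, lambda = 1)
}

#' Fit a gradient-boosted tree classifier
#'
#' @param X numeric feature matrix (no missing values; standardize first,
#'   see [fit_preprocessor]).
#' @param y binary 0/1 outcome vector.
#' @param params hyperparameter list, see [gbt_default_params]; partial
#'   lists are completed with defaults.
#' @param seed RNG seed driving row/column subsampling.
#' @return an object of class `gbt_model`.
#' @export
gbt_fit <- function(X, y, params = list(), seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X))
    stop_fracdem("X must not contain missing values (impute first)",
                 class = "fracdem_ml_error")
  if (length(y) != nrow(X) || !all(y %in% c(0, 1)))
    stop_fracdem("y must be a 0/1 vector matching nrow(X)",
                 class = "fracdem_ml_error")
  p <- modifyList(gbt_default_params(), params)
  n <- nrow(X); nf <- ncol(X)
  n_rows <- max(1L, as.integer(round(p$subsample * n)))
  n_cols <- max(1L, as.integer(round(p$colsample_bytree * nf)))
  samples <- with_seed(seed, list(
    rows = lapply(seq_len(p$n_estimators),
                  function(t) sort(sample.int(n, n_rows)) - 1L),
    cols = lapply(seq_len(p$n_estimators),
                  function(t) sort(sample.int(nf, n_cols)) - 1L)))
  fit <- .gbt_fit_cpp(X, as.numeric(y), as.integer(p$n_estimators),
                      as.integer(p$max_depth), p$gamma, p$min_child_weight,
                      p$subsample, p$lambda, p$eta, 0.0,
                      samples$rows, samples$cols)
  structure(list(trees = fit$trees, base_margin = 0.0,
                 n_features = nf, feature_names = colnames(X),
                 params = p, seed = seed),
            class = "gbt_model")
}

#' Predict from a fitted gradient-boosted tree model
#'
#' @param object a `gbt_model`.
#' @param newdata numeric feature matrix.
#' @param type `"prob"` for P(label = 1), `"margin"` for the raw log-odds
#'   margin.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gbt_model <- function(object, newdata, type = c("prob", "margin"),
                              ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$n_features)
    stop_fracdem("newdata has ", ncol(newdata), " features, model expects ",
                 object$n_features, class = "fracdem_ml_error")
  m <- .gbt_predict_cpp(object$trees, newdata, object$base_margin)
  if (type == "margin") as.numeric(m) else 1 / (1 + exp(-as.numeric(m)))
}

#' Exact tree SHAP attributions
#'
#' Path-dependent SHAP values in log-odds margin units, with the training
#' set (through per-node covers recorded at fit time) as background.  Local
#' accuracy holds: `base_value + rowSums(phi)` equals the margin prediction
#' for every row.
#'
#' @param model a `gbt_model`.
#' @param X numeric feature matrix (preprocessed like the training data).
#' @return list with `phi` (rows x features attribution matrix) and
#'   `base_value` (expected margin over the training background).
#' @export
gbt_shap <- function(model, X) {
  stopifnot(inherits(model, "gbt_model"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != model$n_features)
    stop_fracdem("X has ", ncol(X), " features, model expects ",
                 model$n_features, class = "fracdem_ml_error")
  out <- .gbt_shap_cpp(model$trees, X, model$base_margin, model$n_features)
  colnames(out$phi) <- model$feature_names
  out
}

#' @export
print.gbt_model <- function(x, ...) {
  n_leaves <- sum(vapply(x$trees, function(t) sum(t$feature < 0), numeric(1)))
  cat(sprintf("<gbt_model> %d trees (max_depth %d, eta %g), %d features, %d leaves total\n",
              length(x$trees), x$params$max_depth, x$params$eta,
              x$n_features, n_leaves))
  invisible(x)
}
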