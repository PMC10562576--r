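# Leakage-free preprocessing: mean imputation and z-standardization whose
# statistics are learned on training rows only and then applied unchanged to
# validation/test rows.

#' Fit the imputation / standardization model on training rows
#'
#' Per-feature means and standard deviations are computed ignoring missing
#' entries; missing test-time values are imputed with the training mean
#' (hence standardize to exactly 0), and constant features transform to 0
#' rather than dividing by zero.
#'
#' @param X numeric training matrix (rows = subjects), possibly with `NA`s.
#' @return an object of class `preprocess_model` with fields `center`
#'   (imputation/centering means) and `scale` (standard deviations, 0 kept
#'   as a constant-column marker).
#' @export
fit_preprocessor <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L)
    stop_fracdem("need >= 2 training rows", class = "fracdem_ml_error")
  all_missing <- apply(X, 2L, function(col) all(is.na(col)))
  if (any(all_missing))
    stop_fracdem("feature(s) entirely missing in training data: ",
                 paste(colnames(X)[all_missing], collapse = ", "),
                 class = "fracdem_ml_error")
  center <- colMeans(X, na.rm = TRUE)
  # population (1/n) standard deviation: the transformed training column has
  # unit variance in the scaler's own sense, and a 2-row column (1, 3) maps
  # to exactly (-1, 1)
  scale <- apply(X, 2L, function(col) {
    col <- col[!is.na(col)]
    sqrt(mean((col - mean(col))^2))
  })
  structure(list(center = center, scale = scale,
                 feature_names = colnames(X)),
            class = "preprocess_model")
}

#' Apply a fitted preprocessor
#'
#' @param model a `preprocess_model`.
#' @param X numeric matrix with the same columns as the training data.
#' @return imputed, standardized matrix (no `NA`s).
#' @export
apply_preprocessor <- function(model, X) {
  stopifnot(inherits(model, "preprocess_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$center))
    stop_fracdem("column count mismatch with preprocessor",
                 class = "fracdem_ml_error")
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    x[is.na(x)] <- model$center[j]
    X[, j] <- if (model$scale[j] > 0)
      (x - model$center[j]) / model$scale[j] else 0
  }
  X
}
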