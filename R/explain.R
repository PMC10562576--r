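# SHAP-based model explanation aggregated over validation repetitions:
# per-repetition global feature importances (mean |SHAP| across test
# subjects), their median over repetitions as the final ranking, category
# averages, and the top-two comparison test.

#' SHAP attributions for a test set
#'
#' Thin wrapper around [gbt_shap] that enforces the tree-model contract.
#'
#' @param model a fitted `gbt_model` (tree ensembles only).
#' @param X preprocessed test feature matrix (>= 1 row).
#' @return list with `phi` and `base_value` (see [gbt_shap]).
#' @export
shap_on_test <- function(model, X) {
  if (!inherits(model, "gbt_model"))
    stop_fracdem("SHAP attribution is only supported for tree-ensemble ",
                 "models (gbt_model)", class = "fracdem_shap_error")
  if (!nrow(as.matrix(X)))
    stop_fracdem("need at least one test row", class = "fracdem_shap_error")
  gbt_shap(model, X)
}

#' Global feature importance across repetitions
#'
#' For every repetition, a feature's global SHAP value is the mean absolute
#' attribution across that repetition's test subjects; the final importance
#' is the median of these over repetitions, and features are ranked by it
#' in descending order.
#'
#' @param shap_list list of per-repetition SHAP matrices (subjects x
#'   features), e.g. `lapply(nested_result, function(r) r$shap)`.
#' @return an object of class `importance_summary`: list with
#'   `per_repetition` (repetitions x features matrix), `median` (named
#'   vector) and `ranking` (feature names, most important first).
#' @export
global_importance <- function(shap_list) {
  if (!length(shap_list))
    stop_fracdem("need at least one repetition", class = "fracdem_shap_error")
  per_rep <- t(vapply(shap_list, function(phi) colMeans(abs(phi)),
                      numeric(ncol(shap_list[[1L]]))))
  colnames(per_rep) <- colnames(shap_list[[1L]])
  med <- apply(per_rep, 2L, median)
  structure(list(per_repetition = per_rep, median = med,
                 ranking = names(sort(med, decreasing = TRUE))),
            class = "importance_summary")
}

#' Per-category importance
#'
#' A category's value in a repetition is the sum of its member features'
#' global SHAP values divided by the member count (their mean), so a
#' category value always lies between its members' values.
#'
#' @param summary an `importance_summary`.
#' @param categories named character vector mapping every feature to its
#'   category.
#' @return list with `per_repetition` (repetitions x categories matrix) and
#'   `median` (named vector).
#' @export
category_importance <- function(summary, categories) {
  stopifnot(inherits(summary, "importance_summary"))
  feats <- colnames(summary$per_repetition)
  unmapped <- setdiff(feats, names(categories))
  if (length(unmapped))
    stop_fracdem("features missing from the category map: ",
                 paste(unmapped, collapse = ", "),
                 class = "fracdem_shap_error")
  cats <- unique(categories[feats])
  per_rep <- vapply(cats, function(cat) {
    members <- feats[categories[feats] == cat]
    rowMeans(summary$per_repetition[, members, drop = FALSE])
  }, numeric(nrow(summary$per_repetition)))
  per_rep <- matrix(per_rep, ncol = length(cats),
                    dimnames = list(NULL, cats))
  list(per_repetition = per_rep, median = apply(per_rep, 2L, median))
}

#' Compare the two top-ranked features
#'
#' One-tailed Wilcoxon signed-rank test of the paired per-repetition global
#' SHAP values of the first- versus second-ranked feature (ranking by the
#' median over repetitions).
#'
#' @param summary an `importance_summary` with >= 2 features and >= 5
#'   repetitions.
#' @return list with `first`, `second` (feature names) and `p_value`.
#' @export
compare_top_two <- function(summary) {
  stopifnot(inherits(summary, "importance_summary"))
  if (ncol(summary$per_repetition) < 2L)
    stop_fracdem("need at least two features", class = "fracdem_shap_error")
  if (nrow(summary$per_repetition) < 5L)
    stop_fracdem("need at least five repetitions",
                 class = "fracdem_shap_error")
  first <- summary$ranking[1L]; second <- summary$ranking[2L]
  d <- summary$per_repetition[, first] - summary$per_repetition[, second]
  list(first = first, second = second,
       p_value = signed_rank_greater(d)$p_value)
}

#' Per-feature importance table
#'
#' @param summary an `importance_summary`.
#' @param categories optional feature -> category map to include.
#' @return data.frame with feature, category, median and quartiles of the
#'   per-repetition global SHAP values, ranked by median importance.
#' @export
importance_table <- function(summary, categories = NULL) {
  stopifnot(inherits(summary, "importance_summary"))
  pr <- summary$per_repetition
  out <- data.frame(
    feature = summary$ranking,
    category = if (is.null(categories)) NA_character_
               else unname(categories[summary$ranking]),
    median = unname(summary$median[summary$ranking]),
    q25 = apply(pr[, summary$ranking, drop = FALSE], 2L, quantile,
                probs = 0.25, names = FALSE),
    q75 = apply(pr[, summary$ranking, drop = FALSE], 2L, quantile,
                probs = 0.75, names = FALSE))
  rownames(out) <- NULL
  out
}

#' @export
print.importance_summary <- function(x, ...) {
  cat("<importance_summary>", nrow(x$per_repetition), "repetitions,",
      ncol(x$per_repetition), "features\ntop 5:",
      paste(head(x$ranking, 5L), collapse = ", "), "\n")
  invisible(x)
}
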