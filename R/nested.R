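# Repeated stratified bootstrap nested validation.
#
# Outer loop: stratified bootstrap resampling — within each outcome class,
# the class's own count of subjects is drawn with replacement, so every
# outer training multiset carries exactly the cohort's class proportions;
# the out-of-bag (OOB) subjects, never drawn in either class, form the outer
# test set.  Inner loop: subject-level stratified 5-fold CV on the unique
# training subjects (all bootstrap copies of a subject share its fold,
# preventing leakage) drives a random search over the published
# hyperparameter grid.  Preprocessing is refit inside every training
# context; the winning configuration is refit on the full outer training
# multiset and evaluated on the OOB set only.

#' The published hyperparameter grid
#'
#' Cartesian product of gamma (0.6, 0.7, 0.8), colsample_bytree (0.25, 0.5,
#' 0.75, 1), max_depth (2, 3, 4), min_child_weight (2, 3, 5), n_estimators
#' (5, 10, 20, 100) and subsample (0.1, 0.2, 0.4): 1296 configurations.
#'
#' @return data.frame with 1296 rows, one column per hyperparameter.
#' @export
hyperparameter_grid <- function() {
  expand.grid(gamma = c(0.6, 0.7, 0.8),
              colsample_bytree = c(0.25, 0.5, 0.75, 1),
              max_depth = c(2, 3, 4),
              min_child_weight = c(2, 3, 5),
              n_estimators = c(5, 10, 20, 100),
              subsample = c(0.1, 0.2, 0.4),
              KEEP.OUT.ATTRS = FALSE)
}

#' Stratified bootstrap outer split
#'
#' Within each class independently, that class's subject count is drawn
#' with replacement; the OOB set is every subject (of either class) never
#' drawn.  If the OOB set lacks a class — AUC would be undefined — the draw
#' is repeated with an incremented seed and the event is logged.
#'
#' @param table a `feature_table` with at least 5 subjects per class.
#' @param seed RNG seed.
#' @return an object of class `outer_split`: list with `train_idx` (row
#'   multiset, size = cohort size), `test_idx` (OOB rows), `seed`,
#'   `redraws`.
#' @export
stratified_bootstrap_split <- function(table, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  lab <- table$data$label
  if (min(table(lab)) < 5L)
    stop_fracdem("need >= 5 subjects per class", class = "fracdem_ml_error")
  idx_pos <- which(lab == 1); idx_neg <- which(lab == 0)
  redraws <- 0L
  repeat {
    drawn <- with_seed(seed + redraws, {
      c(sample(idx_neg, length(idx_neg), replace = TRUE),
        sample(idx_pos, length(idx_pos), replace = TRUE))
    })
    test_idx <- setdiff(seq_along(lab), unique(drawn))
    if (length(unique(lab[test_idx])) == 2L) break
    redraws <- redraws + 1L
    message("outer split seed ", seed, ": one-class OOB set, redrawing (",
            redraws, ")")
  }
  structure(list(train_idx = drawn, test_idx = test_idx,
                 seed = seed, redraws = redraws),
            class = "outer_split")
}

#' Subject-level stratified k-fold assignment
#'
#' Unique subjects are partitioned into `k` stratified folds (per-class
#' round-robin after a shuffled ordering), and every bootstrap copy of a
#' subject inherits its subject's fold — the inner CV therefore never sees
#' the same subject on both sides of a split.
#'
#' @param subject_ids subject identifiers, possibly with repetitions.
#' @param labels 0/1 labels aligned with `subject_ids`.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return named integer vector: fold (1..k) per unique subject.
#' @export
subject_level_folds <- function(subject_ids, labels, k = 5L, seed = 1L) {
  u <- !duplicated(subject_ids)
  ids <- subject_ids[u]; lab <- labels[u]
  if (length(ids) < k)
    stop_fracdem("fewer unique subjects (", length(ids), ") than folds (",
                 k, ")", class = "fracdem_ml_error")
  folds <- integer(length(ids)); names(folds) <- ids
  with_seed(seed, {
    start <- 0L
    for (cl in c(0, 1)) {
      members <- sample(which(lab == cl))
      # continuing the round-robin across classes keeps fold sizes within 1
      folds[members] <- ((start + seq_along(members) - 1L) %% k) + 1L
      start <- start + length(members)
    }
  })
  folds
}

#' Hyperparameter random search under subject-level inner CV
#'
#' Samples `n_candidates` distinct points of [hyperparameter_grid] and
#' scores each by the mean validation AUC over `k` subject-level folds of
#' the outer training multiset, refitting the preprocessor on every inner
#' training set.  Folds whose validation set is one-class contribute no
#' AUC; candidates with no scorable fold are discarded.  Ties are broken by
#' fewer trees, then shallower trees, then sampling order.
#'
#' @param X raw (unpreprocessed) feature matrix of the outer training
#'   multiset.
#' @param y 0/1 labels aligned with `X`.
#' @param subject_ids subject ids aligned with `X` (repetitions allowed).
#' @param n_candidates number of distinct grid points to try (1296 =
#'   exhaustive).
#' @param seed RNG seed.
#' @param k inner folds (default 5).
#' @param grid hyperparameter grid (default [hyperparameter_grid]).
#' @return list with `params` (chosen hyperparameters as a list),
#'   `inner_auc` (its mean validation AUC) and `searched` (per-candidate
#'   data.frame).
#' @export
random_search <- function(X, y, subject_ids, n_candidates = 50L, seed = 1L,
                          k = 5L, grid = hyperparameter_grid()) {
  X <- as.matrix(X)
  if (!is_count(n_candidates) || n_candidates < 1L)
    stop_fracdem("n_candidates must be a positive integer",
                 class = "fracdem_ml_error")
  n_candidates <- min(n_candidates, nrow(grid))
  seeds <- with_seed(seed, {
    cand <- sample.int(nrow(grid), n_candidates)
    fold_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    fit_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   n_candidates * k),
                        nrow = n_candidates)
    list(cand = cand, fold_seed = fold_seed, fit_seeds = fit_seeds)
  })
  folds <- subject_level_folds(subject_ids, y, k = k,
                               seed = seeds$fold_seed)
  fold_of_row <- folds[subject_ids]

  mean_auc <- rep(NA_real_, n_candidates)
  for (ci in seq_len(n_candidates)) {
    params <- as.list(grid[seeds$cand[ci], ])
    aucs <- c()
    for (f in seq_len(k)) {
      tr <- which(fold_of_row != f)
      va_rows <- which(fold_of_row == f & !duplicated(subject_ids))
      if (!length(tr) || length(unique(y[va_rows])) < 2L ||
          length(unique(y[tr])) < 2L) next
      prep <- fit_preprocessor(X[tr, , drop = FALSE])
      model <- gbt_fit(apply_preprocessor(prep, X[tr, , drop = FALSE]),
                       y[tr], params, seed = seeds$fit_seeds[ci, f])
      sc <- predict(model, apply_preprocessor(prep, X[va_rows, , drop = FALSE]))
      aucs <- c(aucs, roc_and_auc(y[va_rows], sc)$auc)
    }
    if (length(aucs)) mean_auc[ci] <- mean(aucs)
  }
  if (all(is.na(mean_auc)))
    stop_fracdem("no hyperparameter candidate could be scored",
                 class = "fracdem_ml_error")
  searched <- cbind(grid[seeds$cand, ], inner_auc = mean_auc,
                    order = seq_len(n_candidates))
  ok <- which(!is.na(mean_auc))
  best <- ok[order(-mean_auc[ok], searched$n_estimators[ok],
                   searched$max_depth[ok], searched$order[ok])][1L]
  list(params = as.list(grid[seeds$cand[best], ]),
       inner_auc = mean_auc[best], searched = searched)
}

#' Run the repeated stratified bootstrap nested validation
#'
#' For each repetition: a stratified bootstrap outer split (seed
#' `base_seed + r`), hyperparameter random search by subject-level inner CV
#' on the outer training multiset, preprocessing and final model refit on
#' the full outer training multiset, and evaluation — probabilities, AUC,
#' ROC coordinates and exact tree SHAP attributions — on the out-of-bag
#' subjects only.  Leakage and stratification audits run on every
#' repetition.
#'
#' @param table a `feature_table`.
#' @param n_repetitions number of bootstrap repetitions (study protocol:
#'   100).
#' @param n_candidates random-search budget per repetition (default 50).
#' @param base_seed integer seed; repetition r uses `base_seed + r`.
#' @param k inner folds (default 5).
#' @return an object of class `nested_result`: list of per-repetition
#'   results (each with `seed`, `split`, `params`, `inner_auc`, `test_ids`,
#'   `labels`, `scores`, `margins`, `auc`, `curve`, `shap`, `shap_base`)
#'   plus attributes describing the run.
#' @export
run_nested_validation <- function(table, n_repetitions = 100L,
                                  n_candidates = 50L, base_seed = 1L,
                                  k = 5L) {
  stopifnot(inherits(table, "feature_table"))
  feats <- feature_matrix(table)
  lab <- table$data$label
  ids <- table$data$subject_id

  reps <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    rep_seed <- base_seed + r
    split <- stratified_bootstrap_split(table, rep_seed)
    audit_split(split, lab)

    tr <- split$train_idx; te <- split$test_idx
    search <- random_search(feats[tr, , drop = FALSE], lab[tr], ids[tr],
                            n_candidates = n_candidates,
                            seed = rep_seed, k = k)
    prep <- fit_preprocessor(feats[tr, , drop = FALSE])
    final_seed <- (rep_seed * 2654435L) %% (.Machine$integer.max - 1L) + 1L
    model <- gbt_fit(apply_preprocessor(prep, feats[tr, , drop = FALSE]),
                     lab[tr], search$params, seed = final_seed)
    Xte <- apply_preprocessor(prep, feats[te, , drop = FALSE])
    scores <- predict(model, Xte)
    margins <- predict(model, Xte, type = "margin")
    roc <- roc_and_auc(lab[te], scores)
    shap <- gbt_shap(model, Xte)
    rownames(shap$phi) <- ids[te]

    reps[[r]] <- structure(
      list(seed = rep_seed, split = split, params = search$params,
           inner_auc = search$inner_auc,
           train_label_counts = c("0" = sum(lab[tr] == 0),
                                  "1" = sum(lab[tr] == 1)),
           test_ids = ids[te],
           labels = lab[te], scores = scores, margins = margins,
           auc = roc$auc, curve = roc$curve, shap = shap$phi,
           shap_base = shap$base_value),
      class = "repetition_result")
  }
  structure(reps, class = "nested_result",
            n_repetitions = n_repetitions, n_candidates = n_candidates,
            base_seed = base_seed, k = k,
            feature_names = names(table$categories),
            categories = table$categories)
}

# leakage + stratification audits; errors are programming-bug guards
audit_split <- function(split, labels) {
  if (length(intersect(split$test_idx, split$train_idx)))
    stop_fracdem("leakage: OOB subject present in the training multiset",
                 class = "fracdem_audit_error")
  tr_counts <- table(factor(labels[split$train_idx], levels = c(0, 1)))
  all_counts <- table(factor(labels, levels = c(0, 1)))
  if (!identical(as.integer(tr_counts), as.integer(all_counts)))
    stop_fracdem("stratification: training class counts differ from cohort",
                 class = "fracdem_audit_error")
  invisible(TRUE)
}

#' @export
print.nested_result <- function(x, ...) {
  aucs <- vapply(x, `[[`, numeric(1), "auc")
  s <- summarize_auc(aucs)
  cat(sprintf("<nested_result> %d repetitions | mean AUC %.3f (90%% CI %.3f-%.3f)\n",
              length(x), s$mean, s$ci[1], s$ci[2]))
  invisible(x)
}
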