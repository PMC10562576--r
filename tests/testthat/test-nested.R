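# stratified bootstrap splits, subject-level folds, random search, and the
# repeated nested validation

test_that("the hyperparameter grid is the printed 1296-point space", {
  g <- hyperparameter_grid()
  expect_equal(nrow(g), 1296)
  expect_setequal(unique(g$gamma), c(0.6, 0.7, 0.8))
  expect_setequal(unique(g$colsample_bytree), c(0.25, 0.5, 0.75, 1))
  expect_setequal(unique(g$max_depth), c(2, 3, 4))
  expect_setequal(unique(g$min_child_weight), c(2, 3, 5))
  expect_setequal(unique(g$n_estimators), c(5, 10, 20, 100))
  expect_setequal(unique(g$subsample), c(0.1, 0.2, 0.4))
  expect_equal(nrow(unique(g)), 1296)
})

test_that("stratified bootstrap splits keep exact class counts and clean OOB", {
  tab <- simulate_cohort(seed = 1)
  sp <- stratified_bootstrap_split(tab, seed = 5)
  expect_length(sp$train_idx, 64)
  lab <- tab$data$label
  expect_equal(sum(lab[sp$train_idx] == 0), 46)
  expect_equal(sum(lab[sp$train_idx] == 1), 18)
  expect_length(intersect(sp$test_idx, sp$train_idx), 0)
  expect_setequal(union(unique(sp$train_idx), sp$test_idx), 1:64)
  expect_equal(length(unique(lab[sp$test_idx])), 2)
  expect_identical(sp, stratified_bootstrap_split(tab, seed = 5))

  small <- simulate_cohort(n_neg = 6, n_pos = 5, seed = 2)
  small$data$label[which(small$data$label == 1)[1]] <- 0  # now 4 positives
  expect_error(stratified_bootstrap_split(small),
               class = "fracdem_ml_error")
})

test_that("mean OOB size matches the bootstrap expectation over 200 seeds", {
  tab <- simulate_cohort(seed = 3)
  sizes <- vapply(1:200, function(s)
    length(stratified_bootstrap_split(tab, seed = 10000 + s)$test_idx),
    numeric(1))
  expected <- 46 * (45 / 46)^46 + 18 * (17 / 18)^18
  expect_lt(abs(mean(sizes) - expected), 3 * sd(sizes) / sqrt(200))
})

test_that("subject-level folds are stratified partitions shared by copies", {
  ids <- sprintf("P%02d", 1:40)
  lab <- rep(c(0, 1), c(30, 10))
  folds <- subject_level_folds(ids, lab, k = 5, seed = 4)
  expect_setequal(names(folds), ids)
  expect_true(all(table(folds) == 8))
  for (f in 1:5)
    expect_equal(sum(lab[match(names(folds)[folds == f], ids)]), 2)

  # bootstrap copies inherit their subject's fold by construction
  boot <- sample(ids, 60, replace = TRUE)
  per_copy <- folds[boot]
  expect_true(all(tapply(per_copy, boot, function(v) length(unique(v))) == 1))

  expect_error(subject_level_folds(ids[1:3], lab[1:3], k = 5),
               class = "fracdem_ml_error")
})

test_that("random search honors its budget, tie-breaks and degenerate cases", {
  tab <- make_separable_cohort(seed = 6)
  X <- feature_values(tab); y <- tab$data$label; ids <- tab$data$subject_id

  # a single candidate is returned regardless of score
  g1 <- hyperparameter_grid()[77, , drop = FALSE]
  rs1 <- random_search(X, y, ids, n_candidates = 1, seed = 2, grid = g1)
  expect_equal(rs1$params, as.list(g1[1, ]))

  # a small custom grid searched exhaustively: every point scored once
  g4 <- hyperparameter_grid()[c(4, 400, 800, 1200), ]
  rs4 <- random_search(X, y, ids, n_candidates = 10, seed = 3, grid = g4)
  expect_equal(nrow(rs4$searched), 4)
  expect_equal(sum(!is.na(rs4$searched$inner_auc)), 4)

  # strong signal: the chosen model separates well in inner CV
  rs <- random_search(X, y, ids, n_candidates = 10, seed = 4)
  expect_gt(rs$inner_auc, 0.8)
})

test_that("nested validation is deterministic, leak-free and well-formed", {
  tab <- simulate_cohort(seed = 8)
  res <- run_nested_validation(tab, n_repetitions = 4, n_candidates = 5,
                               base_seed = 50)
  res2 <- run_nested_validation(tab, n_repetitions = 4, n_candidates = 5,
                                base_seed = 50)
  expect_identical(vapply(res, `[[`, numeric(1), "auc"),
                   vapply(res2, `[[`, numeric(1), "auc"))

  lab <- tab$data$label
  full_center <- colMeans(feature_values(tab))
  for (r in res) {
    expect_length(intersect(r$split$test_idx, r$split$train_idx), 0)
    expect_equal(sum(lab[r$split$train_idx] == 0), 46)
    expect_equal(sum(lab[r$split$train_idx] == 1), 18)
    expect_length(r$scores, length(r$split$test_idx))
    expect_true(r$auc >= 0 && r$auc <= 1)
    expect_true(nrow(merge(as.data.frame(r$params),
                           hyperparameter_grid())) == 1)
    # guard against accidental full-table preprocessing
    train_center <- colMeans(feature_values(tab)[r$split$train_idx, ])
    expect_false(isTRUE(all.equal(train_center, full_center)))
    # SHAP rows align with the OOB set and satisfy local accuracy
    expect_equal(rownames(r$shap), r$test_ids)
    expect_lt(max(abs(r$shap_base + rowSums(r$shap) - r$margins)), 1e-8)
  }
})

test_that("the split audit catches corrupted splits", {
  tab <- simulate_cohort(seed = 9)
  sp <- stratified_bootstrap_split(tab, seed = 1)
  lab <- tab$data$label
  bad_leak <- sp; bad_leak$train_idx[1] <- sp$test_idx[1]
  expect_error(fracdem:::audit_split(bad_leak, lab),
               class = "fracdem_audit_error")
  bad_strat <- sp
  bad_strat$train_idx <- rep(which(lab == 0)[1], 64)
  bad_strat$test_idx <- integer(0)
  expect_error(fracdem:::audit_split(bad_strat, lab),
               class = "fracdem_audit_error")
})
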