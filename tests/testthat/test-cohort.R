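# synthetic cohort simulator

test_that("the default specification has the published structure and values", {
  spec <- default_cohort_spec()
  expect_equal(nrow(spec), 21)
  expect_equal(as.integer(table(spec$category)[c("demographic",
                                                 "neuropsychological",
                                                 "visual_mri",
                                                 "quantitative_mri")]),
               c(3L, 6L, 4L, 8L))
  gm <- spec[spec$name == "gm_fd", ]
  expect_equal(c(gm$mean_neg, gm$sd_neg, gm$mean_pos, gm$sd_pos),
               c(2.34, 0.02, 2.33, 0.02))
  sdmt <- spec[spec$name == "sdmt", ]
  expect_equal(c(sdmt$mean_neg, sdmt$mean_pos), c(39.18, 31.18))
  hip <- spec[spec$name == "hippocampal_volume", ]
  expect_equal(c(hip$mean_neg, hip$mean_pos), c(0.0023, 0.0020))
  sex <- spec[spec$name == "sex", ]
  expect_equal(c(sex$mean_neg, sex$mean_pos), c(22 / 46, 8 / 18))
})

test_that("simulated cohorts are reproducible and correctly sized", {
  a <- simulate_cohort(seed = 42)
  b <- simulate_cohort(seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a$data), 64)
  expect_equal(sum(a$data$label), 18)
  expect_equal(ncol(a$data), 23)  # subject_id + label + 21 features

  c30 <- simulate_cohort(n_neg = 20, n_pos = 10, seed = 1)
  expect_equal(mean(c30$data$label), 1 / 3)
  expect_error(simulate_cohort(n_neg = 3, n_pos = 10),
               class = "fracdem_cohort_error")
})

test_that("simulated values respect the published ranges", {
  tab <- simulate_cohort(seed = 8)
  spec <- default_cohort_spec()
  for (i in seq_len(nrow(spec))) {
    v <- tab$data[[spec$name[i]]]
    lo <- min(spec$min_neg[i], spec$min_pos[i])
    hi <- max(spec$max_neg[i], spec$max_pos[i])
    expect_true(all(v >= lo & v <= hi), info = spec$name[i])
    if (spec$type[i] != "continuous")
      expect_true(all(v == round(v)), info = spec$name[i])
  }
})

test_that("large-sample group means match the truncated-Gaussian expectation", {
  # closed-form mean of a range-truncated Gaussian (independent oracle);
  # for heavily skewed ranges (Stroop, TMT-A) truncation shifts the mean by
  # well over 3 SE at n = 1000, so the exact expectation is the right target
  trunc_mean <- function(m, s, lo, hi) {
    a <- (lo - m) / s; b <- (hi - m) / s
    m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  tab <- simulate_cohort(n_neg = 1000, n_pos = 1000, seed = 77)
  spec <- default_cohort_spec()
  cont <- spec[spec$type == "continuous", ]
  for (i in seq_len(nrow(cont))) {
    v <- tab$data[[cont$name[i]]]
    for (g in c("neg", "pos")) {
      obs <- mean(v[tab$data$label == (g == "pos")])
      expected <- trunc_mean(cont[[paste0("mean_", g)]][i],
                             cont[[paste0("sd_", g)]][i],
                             cont[[paste0("min_", g)]][i],
                             cont[[paste0("max_", g)]][i])
      se <- cont[[paste0("sd_", g)]][i] / sqrt(1000)
      expect_lt(abs(obs - expected), 4 * se)
    }
  }
})

test_that("missingness injection is MCAR at the requested rate", {
  tab <- simulate_cohort(seed = 5)
  expect_identical(inject_missingness(tab, 0), tab)

  miss <- inject_missingness(tab, 0.05, seed = 6)
  expect_true(all(!is.na(miss$data$label)))
  n_missing <- sum(is.na(feature_values(miss)))
  # Binomial(1344, 0.05) central 99% interval
  expect_gte(n_missing, qbinom(0.005, 64 * 21, 0.05))
  expect_lte(n_missing, qbinom(0.995, 64 * 21, 0.05))

  again <- inject_missingness(tab, 0.5, seed = 9)
  expect_identical(is.na(feature_values(again)),
                   is.na(feature_values(inject_missingness(tab, 0.5,
                                                           seed = 9))))
  expect_error(inject_missingness(tab, 1), class = "fracdem_cohort_error")
})

test_that("the separable cohort isolates the requested signal", {
  tab <- make_separable_cohort(n_neg = 2000, n_pos = 2000,
                               signal_feature = "gm_fd", effect_sd = 6,
                               seed = 10)
  d <- tab$data
  gm_gap <- mean(d$gm_fd[d$label == 0]) - mean(d$gm_fd[d$label == 1])
  expect_equal(gm_gap / 0.02, 6, tolerance = 0.05)
  # a univariate threshold on the signal attains near-perfect AUC
  expect_gt(roc_and_auc(d$label, -d$gm_fd)$auc, 0.99)
  # all other features carry no signal
  for (f in setdiff(names(tab$categories), "gm_fd")) {
    pooled_sd <- sd(d[[f]])
    gap <- abs(mean(d[[f]][d$label == 0]) - mean(d[[f]][d$label == 1]))
    expect_lt(gap, 0.15 * pooled_sd + 1e-12)
  }
  expect_identical(make_separable_cohort(seed = 3),
                   make_separable_cohort(seed = 3))
  expect_error(make_separable_cohort(signal_feature = "nope"),
               class = "fracdem_cohort_error")
})

test_that("label permutation preserves balance and features", {
  tab <- simulate_cohort(seed = 2)
  perm <- permute_labels(tab, seed = 4)
  expect_equal(sum(perm$data$label), 18)
  expect_identical(perm$data$gm_fd, tab$data$gm_fd)
  expect_false(identical(perm$data$label, tab$data$label))
})

test_that("cohort CSV round-trips, including missing cells", {
  tab <- inject_missingness(simulate_cohort(seed = 3), 0.1, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(tab, f)
  back <- read_cohort_csv(f)
  expect_equal(back$data, tab$data, tolerance = 1e-12)
  expect_identical(back$categories, tab$categories)

  # label column is mandatory and named in the error
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = "S1", age = 70), bad, row.names = FALSE)
  expect_error(read_cohort_csv(bad), regexp = "label",
               class = "fracdem_io_error")
})
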