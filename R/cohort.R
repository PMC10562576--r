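# Synthetic case-control cohort simulator.
#
# The study cohort (64 participants with MCI and moderate-to-severe
# leukoaraiosis; 18 converted to dementia within 2 years) is not publicly
# available, so the prediction pipeline is exercised on synthetic feature
# tables that reproduce the published per-group descriptive statistics:
# mean (SD) [min, max] per feature per outcome group.  Features are drawn
# independently within group (no covariance structure is published), from
# range-truncated Gaussians; ordinal visual scores are rounded and clipped;
# sex is Bernoulli with the per-group female proportion.

FEATURE_CATEGORIES <- c("demographic", "neuropsychological", "visual_mri",
                        "quantitative_mri")

#' Default 21-feature cohort specification
#'
#' One row per feature with per-group (non-transition `neg`, N = 46;
#' transition `pos`, N = 18) mean, SD, min and max, the feature category
#' (3 demographic, 6 neuropsychological, 4 visually assessed MRI, 8
#' quantitative MRI) and the sampling type (`continuous`, `binary`,
#' `ordinal`).  Sex is encoded 0 = male, 1 = female; its "mean" is the
#' female proportion (22/46 and 8/18).  Volumes are eTIV-normalized
#' (dimensionless); MD is in 1e-3 mm^2/s.
#'
#' @return a `data.frame` of class `cohort_spec` with columns `name`,
#'   `category`, `type`, `mean_neg`, `sd_neg`, `min_neg`, `max_neg`,
#'   `mean_pos`, `sd_pos`, `min_pos`, `max_pos`.
#' @export
default_cohort_spec <- function() {
  row <- function(name, category, type, neg, pos)
    data.frame(name = name, category = category, type = type,
               mean_neg = neg[1], sd_neg = neg[2], min_neg = neg[3],
               max_neg = neg[4],
               mean_pos = pos[1], sd_pos = pos[2], min_pos = pos[3],
               max_pos = pos[4])
  spec <- rbind(
    row("age", "demographic", "continuous",
        c(73.96, 6.67, 61.12, 89.03), c(76.34, 6.693, 59.80, 84.09)),
    row("sex", "demographic", "binary",
        c(22 / 46, NA, 0, 1), c(8 / 18, NA, 0, 1)),
    row("education", "demographic", "continuous",
        c(8.17, 4.25, 3, 18), c(7.44, 4.30, 2, 18)),
    row("moca", "neuropsychological", "continuous",
        c(21.23, 4.62, 11.95, 29.29), c(18.93, 3.95, 13.10, 25.24)),
    row("rocf", "neuropsychological", "continuous",
        c(23.68, 7.21, 5.59, 35.58), c(21.27, 10.61, 4, 36)),
    row("sdmt", "neuropsychological", "continuous",
        c(39.18, 10.03, 22.02, 59.94), c(31.18, 5.38, 24.67, 43.49)),
    row("stroop", "neuropsychological", "continuous",
        c(33.44, 23.81, -3.45, 114.57), c(51.59, 36.02, 8.83, 155.09)),
    row("tmt_a", "neuropsychological", "continuous",
        c(61.47, 47.97, 3.77, 202.2), c(64.47, 43.15, 8.42, 152.92)),
    row("vs", "neuropsychological", "continuous",
        c(32.84, 8.61, 14.3, 50.17), c(29.08, 7.78, 15.41, 41.27)),
    row("lacunes", "visual_mri", "ordinal",
        c(2.02, 0.80, 1, 3), c(2.28, 0.83, 1, 3)),
    row("microbleeds", "visual_mri", "ordinal",
        c(0.91, 2.57, 0, 15), c(2.24, 5.77, 0, 18)),
    row("epvs_bg", "visual_mri", "ordinal",
        c(1.67, 0.82, 0, 4), c(1.83, 0.62, 1, 3)),
    row("epvs_cso", "visual_mri", "ordinal",
        c(1.89, 0.77, 1, 3), c(1.44, 0.70, 1, 3)),
    row("wm_lesion_load", "quantitative_mri", "continuous",
        c(0.07, 0.04, 0.01, 0.20), c(0.09, 0.05, 0.02, 0.20)),
    row("wm_volume", "quantitative_mri", "continuous",
        c(0.15, 0.01, 0.12, 0.17), c(0.14, 0.01, 0.13, 0.16)),
    row("gm_volume", "quantitative_mri", "continuous",
        c(0.12, 0.01, 0.10, 0.14), c(0.11, 0.01, 0.10, 0.12)),
    row("hippocampal_volume", "quantitative_mri", "continuous",
        c(0.0023, 0.0005, 0.0010, 0.0031), c(0.0020, 0.0002, 0.0020, 0.0024)),
    row("wm_fd", "quantitative_mri", "continuous",
        c(2.45, 0.04, 2.35, 2.51), c(2.43, 0.04, 2.36, 2.49)),
    row("gm_fd", "quantitative_mri", "continuous",
        c(2.34, 0.02, 2.30, 2.38), c(2.33, 0.02, 2.27, 2.36)),
    row("median_fa", "quantitative_mri", "continuous",
        c(0.37, 0.02, 0.33, 0.41), c(0.36, 0.02, 0.32, 0.40)),
    row("median_md", "quantitative_mri", "continuous",
        c(0.82, 0.05, 0.7, 0.9), c(0.82, 0.04, 0.8, 0.9)))
  class(spec) <- c("cohort_spec", "data.frame")
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(is.data.frame(spec),
            all(c("name", "category", "type", "mean_neg", "sd_neg",
                  "min_neg", "max_neg", "mean_pos", "sd_pos", "min_pos",
                  "max_pos") %in% names(spec)))
  if (anyDuplicated(spec$name))
    stop_fracdem("duplicate feature names in spec",
                 class = "fracdem_cohort_error")
  if (!all(spec$category %in% FEATURE_CATEGORIES))
    stop_fracdem("unknown feature category", class = "fracdem_cohort_error")
  for (g in c("neg", "pos")) {
    m <- spec[[paste0("mean_", g)]]
    bad <- m < spec[[paste0("min_", g)]] | m > spec[[paste0("max_", g)]]
    if (any(bad))
      stop_fracdem("group mean outside [min, max] for: ",
                   paste(spec$name[bad], collapse = ", "),
                   class = "fracdem_cohort_error")
  }
  invisible(spec)
}

# Truncated-Gaussian sampler by rejection; degenerate sd = 0 (or binary /
# point ranges) handled explicitly.
rtrunc_gauss <- function(n, mean, sd, lo, hi, max_rounds = 10000L) {
  if (n == 0L) return(numeric(0))
  if (!is.finite(sd) || sd <= 0 || lo == hi) return(rep(mean, n))
  out <- numeric(n); need <- seq_len(n); rounds <- 0L
  while (length(need) && rounds < max_rounds) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
    rounds <- rounds + 1L
  }
  if (length(need))
    stop_fracdem("rejection sampling failed (mean/sd incompatible with range)",
                 class = "fracdem_cohort_error")
  out
}

draw_feature <- function(n, type, mean, sd, lo, hi) {
  switch(type,
    continuous = rtrunc_gauss(n, mean, sd, lo, hi),
    binary = as.numeric(runif(n) < mean),
    ordinal = pmin(hi, pmax(lo, round(rtrunc_gauss(n, mean, sd, lo, hi)))),
    stop_fracdem("unknown feature type: ", type,
                 class = "fracdem_cohort_error"))
}

new_feature_table <- function(data, categories) {
  feats <- setdiff(names(data), c("subject_id", "label"))
  stopifnot(all(feats %in% names(categories)))
  if (!all(data$label %in% c(0, 1)) || length(unique(data$label)) < 2L)
    stop_fracdem("labels must be binary with both classes present",
                 class = "fracdem_cohort_error")
  structure(list(data = data, categories = categories[feats]),
            class = "feature_table")
}

#' Simulate a synthetic baseline cohort
#'
#' Draws `n_neg` non-transition (label 0) and `n_pos` transition (label 1)
#' subjects; each feature is sampled independently within group from its
#' specified distribution (see [default_cohort_spec]).  Reproducible for a
#' fixed `seed`.
#'
#' @param spec a `cohort_spec`; default [default_cohort_spec()].
#' @param n_neg,n_pos per-group sample sizes (defaults 46 and 18, the
#'   published group sizes; both must be >= 5).
#' @param seed RNG seed.
#' @return an object of class `feature_table`: list with `data` (a
#'   `data.frame` with `subject_id`, `label`, then one column per feature)
#'   and `categories` (named character vector, feature -> category).
#' @export
#' @examples
#' tab <- simulate_cohort(seed = 1)
#' dim(tab$data)       # 64 x 23
#' sum(tab$data$label) # 18
simulate_cohort <- function(spec = default_cohort_spec(), n_neg = 46L,
                            n_pos = 18L, seed = 1L) {
  validate_cohort_spec(spec)
  if (!is_count(n_neg) || !is_count(n_pos) || n_neg < 5L || n_pos < 5L)
    stop_fracdem("n_neg and n_pos must be integers >= 5",
                 class = "fracdem_cohort_error")
  n <- n_neg + n_pos
  with_seed(seed, {
    cols <- lapply(seq_len(nrow(spec)), function(i) {
      r <- spec[i, ]
      c(draw_feature(n_neg, r$type, r$mean_neg, r$sd_neg, r$min_neg, r$max_neg),
        draw_feature(n_pos, r$type, r$mean_pos, r$sd_pos, r$min_pos, r$max_pos))
    })
    names(cols) <- spec$name
    data <- cbind(data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                             label = rep(c(0, 1), c(n_neg, n_pos))),
                  as.data.frame(cols))
    new_feature_table(data, setNames(spec$category, spec$name))
  })
}

#' Inject missing-completely-at-random missingness
#'
#' Each feature cell is independently set to `NA` with probability `rate`;
#' `subject_id` and `label` are never made missing.  The real study reports
#' the presence of missing values (they are mean-imputed downstream) but not
#' their rate or mechanism, so the rate is a free parameter.
#'
#' @param table a `feature_table`.
#' @param rate missingness probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return a `feature_table` with missing entries.
#' @export
inject_missingness <- function(table, rate, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1)
    stop_fracdem("rate must be in [0, 1)", class = "fracdem_cohort_error")
  if (rate == 0) return(table)
  feats <- names(table$categories)
  with_seed(seed, {
    for (f in feats) {
      miss <- runif(nrow(table$data)) < rate
      table$data[[f]][miss] <- NA_real_
    }
  })
  table
}

#' Simulate a cohort with a single discriminative feature
#'
#' Fixture for signal-recovery tests: every feature is drawn from the
#' non-transition group's distribution in both groups (groups exchangeable)
#' except `signal_feature`, whose distribution in the transition group is
#' shifted downward — mean and truncation bounds alike — by
#' `effect_sd` pooled standard deviations.  Shifting the bounds with the
#' mean keeps the distribution's shape identical across groups, so the
#' realized group-mean difference equals the requested effect size.
#'
#' @param n_neg,n_pos group sizes.
#' @param signal_feature name of the discriminative feature (one of the 21).
#' @param effect_sd effect size in pooled-SD units (>= 0; 0 gives fully
#'   exchangeable groups).
#' @param seed RNG seed.
#' @param spec base specification, default [default_cohort_spec()].
#' @return a `feature_table`.
#' @export
make_separable_cohort <- function(n_neg = 46L, n_pos = 18L,
                                  signal_feature = "gm_fd", effect_sd = 6,
                                  seed = 1L, spec = default_cohort_spec()) {
  validate_cohort_spec(spec)
  if (!signal_feature %in% spec$name)
    stop_fracdem("unknown feature name: ", signal_feature,
                 class = "fracdem_cohort_error")
  if (!is.numeric(effect_sd) || length(effect_sd) != 1L || effect_sd < 0)
    stop_fracdem("effect_sd must be >= 0", class = "fracdem_cohort_error")
  i <- match(signal_feature, spec$name)
  if (spec$type[i] != "continuous")
    stop_fracdem("signal_feature must be continuous",
                 class = "fracdem_cohort_error")
  # both groups inherit the non-transition distribution ...
  spec$mean_pos <- spec$mean_neg; spec$sd_pos <- spec$sd_neg
  spec$min_pos <- spec$min_neg; spec$max_pos <- spec$max_neg
  # ... and the signal feature's positive-group copy is shifted down
  delta <- effect_sd * spec$sd_neg[i]
  spec$mean_pos[i] <- spec$mean_pos[i] - delta
  spec$min_pos[i] <- spec$min_pos[i] - delta
  spec$max_pos[i] <- spec$max_pos[i] - delta
  simulate_cohort(spec, n_neg = n_neg, n_pos = n_pos, seed = seed)
}

#' Permute outcome labels of a feature table
#'
#' Null-calibration fixture: the label column is randomly permuted so no
#' feature carries signal while the class balance is preserved.
#'
#' @param table a `feature_table`.
#' @param seed RNG seed.
#' @return a `feature_table` with permuted labels.
#' @export
permute_labels <- function(table, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  table$data$label <- with_seed(seed, sample(table$data$label))
  table
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects (%d transition, %d non-transition), %d features\n",
              nrow(x$data), sum(x$data$label == 1), sum(x$data$label == 0),
              length(x$categories)))
  cat("categories:", paste(sprintf("%s (%d)", names(table(x$categories)),
                                   table(x$categories)), collapse = ", "), "\n")
  invisible(x)
}

feature_matrix <- function(table) {
  as.matrix(table$data[names(table$categories)])
}

#' Write / read a feature table as CSV
#'
#' Comma-separated, UTF-8, header row (`subject_id`, `label`, then feature
#' columns); empty cells encode missing values.  The feature -> category map
#' is written alongside as JSON (`<path>.categories.json`) and restored on
#' read; if absent, features named as in [default_cohort_spec] fall back to
#' the default map.
#'
#' @param table a `feature_table`.
#' @param path CSV path.
#' @return `write_cohort_csv`: `path`, invisibly. `read_cohort_csv`: a
#'   `feature_table`.
#' @export
write_cohort_csv <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  write.csv(table$data, path, row.names = FALSE, na = "")
  jsonlite::write_json(as.list(table$categories), categories_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

categories_path <- function(path) paste0(path, ".categories.json")

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    stop_fracdem("cohort CSV not found: ", path, class = "fracdem_io_error")
  data <- read.csv(path, check.names = FALSE)
  if (!"label" %in% names(data))
    stop_fracdem("cohort CSV is missing the required `label` column",
                 class = "fracdem_io_error")
  if (!"subject_id" %in% names(data))
    data$subject_id <- sprintf("S%03d", seq_len(nrow(data)))
  feats <- setdiff(names(data), c("subject_id", "label"))
  cats <- if (file.exists(categories_path(path))) {
    unlist(jsonlite::read_json(categories_path(path), simplifyVector = TRUE))
  } else {
    dflt <- default_cohort_spec()
    unknown <- setdiff(feats, dflt$name)
    if (length(unknown))
      stop_fracdem("unknown feature columns (no category map found): ",
                   paste(unknown, collapse = ", "),
                   class = "fracdem_io_error")
    setNames(dflt$category, dflt$name)[feats]
  }
  missing_map <- setdiff(feats, names(cats))
  if (length(missing_map))
    stop_fracdem("feature columns missing from category map: ",
                 paste(missing_map, collapse = ", "),
                 class = "fracdem_io_error")
  for (f in feats) data[[f]] <- as.numeric(data[[f]])
  new_feature_table(data[c("subject_id", "label", feats)], cats[feats])
}
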