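# End-to-end workflow: cohort in, nested validation + evaluation +
# explanation out, with a provenance block sufficient to re-execute the run.

#' Default pipeline configuration
#'
#' Defaults mirror the study protocol: 100 bootstrap repetitions, 5 inner
#' folds, the printed hyperparameter grid, and a random-search budget of 50
#' candidates (the search budget is not published; 1296 is exhaustive).
#'
#' @param ... overrides of any field.
#' @return a named list (class `run_config`).
#' @export
default_run_config <- function(...) {
  cfg <- list(cohort_csv = NULL,       # NULL -> simulate the default cohort
              out_dir = NULL,
              seed = 1L,
              n_repetitions = 100L,
              n_candidates = 50L,
              k = 5L,
              missing_rate = 0,
              n_offsets = 20L,
              grid_step = 0.01)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop_fracdem("unknown config field(s): ", paste(unknown, collapse = ", "),
                 class = "fracdem_config_error")
  structure(modifyList(cfg, overrides), class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with any subset of [default_run_config] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_fracdem("config file not found: ", path,
                 class = "fracdem_config_error")
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_run_config, vals)
}

#' Run the full prediction pipeline
#'
#' Loads (or simulates) the cohort, runs the repeated stratified bootstrap
#' nested validation, evaluates it (mean AUC with 90% CI, Wilcoxon test
#' against chance, median ROC with quartile bands, Youden operating point)
#' and ranks feature and category importances from the per-repetition SHAP
#' attributions.  When `config$out_dir` is set, writes `summary.json`
#' (including a provenance block), `median_roc.csv`,
#' `feature_importance.tsv`, `category_importance.tsv` and a per-repetition
#' `repetitions.json`.
#'
#' @param config a `run_config`, see [default_run_config].
#' @return (invisibly) list with `table`, `nested`, `aucs`, `auc_summary`,
#'   `p_chance`, `median_roc`, `operating_point`, `importance`,
#'   `category_importance`, `summary`.
#' @export
run_full_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  table <- if (is.null(config$cohort_csv)) {
    tab <- simulate_cohort(seed = config$seed)
    if (config$missing_rate > 0)
      tab <- inject_missingness(tab, config$missing_rate,
                                seed = config$seed + 1L)
    tab
  } else read_cohort_csv(config$cohort_csv)

  nested <- run_nested_validation(table,
                                  n_repetitions = config$n_repetitions,
                                  n_candidates = config$n_candidates,
                                  base_seed = config$seed, k = config$k)
  aucs <- vapply(nested, `[[`, numeric(1), "auc")
  auc_summary <- summarize_auc(aucs)
  p_chance <- wilcoxon_vs_chance(aucs)
  mroc <- median_roc(lapply(nested, `[[`, "curve"),
                     grid_step = config$grid_step)
  op <- youden_optimal(mroc)
  imp <- global_importance(lapply(nested, `[[`, "shap"))
  cat_imp <- category_importance(imp, attr(nested, "categories"))
  top2 <- compare_top_two(imp)

  summary <- list(
    n_subjects = nrow(table$data),
    n_transition = sum(table$data$label == 1),
    n_repetitions = config$n_repetitions,
    mean_auc = auc_summary$mean,
    auc_ci90 = auc_summary$ci,
    wilcoxon_p_vs_chance = p_chance,
    operating_point = op,
    top_feature = top2$first,
    second_feature = top2$second,
    top_two_p = top2$p_value,
    feature_importance = as.list(imp$median[imp$ranking]),
    category_importance = as.list(cat_imp$median),
    provenance = list(
      package = "fracdem",
      version = as.character(utils::packageVersion("fracdem")),
      # out_dir is a filesystem location, not scientific provenance; dropping
      # it keeps summaries byte-identical across output locations
      config = unclass(config)[setdiff(names(config), "out_dir")],
      r_version = R.version.string))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(mroc, file.path(config$out_dir, "median_roc.csv"),
              row.names = FALSE)
    imp_tab <- importance_table(imp, attr(nested, "categories"))
    write.table(imp_tab, file.path(config$out_dir, "feature_importance.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    cat_tab <- data.frame(category = names(cat_imp$median),
                          median = unname(cat_imp$median))
    write.table(cat_tab, file.path(config$out_dir, "category_importance.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    rep_info <- lapply(nested, function(r)
      list(seed = r$seed, params = r$params, auc = r$auc,
           oob_ids = r$test_ids, scores = r$scores))
    jsonlite::write_json(rep_info,
                         file.path(config$out_dir, "repetitions.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(table = table, nested = nested, aucs = aucs,
                 auc_summary = auc_summary, p_chance = p_chance,
                 median_roc = mroc, operating_point = op,
                 importance = imp, category_importance = cat_imp,
                 summary = summary))
}
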