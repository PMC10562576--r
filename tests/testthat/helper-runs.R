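# Shared nested-validation runs used by several acceptance criteria (5-8):
# computed once per test session and cached.

.run_cache <- new.env(parent = emptyenv())

# 20 independent permuted-label runs of 20 repetitions each (criterion 5)
null_runs <- function() {
  if (is.null(.run_cache$null)) {
    .run_cache$null <- lapply(1:20, function(run) {
      tab <- permute_labels(simulate_cohort(seed = 1000 + run),
                            seed = 2000 + run)
      run_nested_validation(tab, n_repetitions = 20L, n_candidates = 10L,
                            base_seed = 3000 + run * 100L)
    })
  }
  .run_cache$null
}

# one 20-repetition run on the separable cohort (criterion 6)
signal_run <- function() {
  if (is.null(.run_cache$signal)) {
    tab <- make_separable_cohort(effect_sd = 6, signal_feature = "gm_fd",
                                 seed = 77)
    .run_cache$signal <- run_nested_validation(tab, n_repetitions = 20L,
                                               n_candidates = 10L,
                                               base_seed = 500L)
  }
  .run_cache$signal
}
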