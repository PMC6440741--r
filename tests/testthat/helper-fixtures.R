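# Shared fixtures built in code. The full-scale recovery run used by the
# acceptance tests is expensive (minutes), so it is computed once per test
# session and memoised.

example_fit <- function(t50 = 2.40, slope = 2.05) {
  detectbms:::new_psychfit(t50, slope)
}

# A small behavioural session: grid + trials + simulated behaviour.
small_session <- function(seed = 1L, fit = example_fit(),
                          config = sim_config(n_subjects = 1L)) {
  grid <- derive_intensity_grid(fit)
  trials <- build_trial_table(grid, seed = seed)
  simulate_behaviour(fit, trials, config, seed = seed + 1L)
}

# Tiny BOLD cohort for fast end-to-end unit tests (not acceptance scale).
tiny_cohort_config <- function(seed = 5L, n_subjects = 3L) {
  # n_vols enlarged so single-run fixtures never overrun the scan
  sim_config(n_subjects = n_subjects, n_runs = 2L, n_vols = 410L,
             dim = c(10L, 10L, 10L), region_size = c(4L, 3L, 2L),
             seed = seed)
}

# The acceptance-scale recovery run (12 subjects, 20^3 lattice, five
# 60-voxel generator regions, amplitude 1% vs noise SD 1%), shared by the
# A1/A2/A6 acceptance blocks.
acceptance_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_recovery_pipeline(sim_config(seed = 7L),
                                      ep_samples = 5000L)
    }
    cache
  }
})
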