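# Shared fixtures, computed once per test session and cached. The clock
# fixture is the "clock recovery" study: 2000 subjects, 200 candidate
# proteins of which 20 carry age signal tied to a single latent organ
# offset, trained at desk-scale search settings (30 trials, 5 folds).

.fixture_cache <- new.env(parent = emptyenv())

clock_recovery_config <- function(seed = 1) {
  sim_config(
    n_subjects = 2000, organs = "brain", n_proteins_per_organ = 100,
    frac_age_informative = 0.2, n_background_proteins = 100, seed = seed
  )
}

clock_fixture <- function() {
  if (is.null(.fixture_cache$clock)) {
    cfg <- clock_recovery_config(seed = 1)
    sim <- simulate_cohort(cfg)
    prep <- preprocess_cohort(sim$cohort)
    clock <- train_clock(prep$cohort, prep$proteins,
                         space = clock_search_space(), seed = 1)
    .fixture_cache$clock <- list(cfg = cfg, sim = sim, prep = prep,
                                 clock = clock)
  }
  .fixture_cache$clock
}

# Small cohort reused by fast unit tests (one organ, strong signal).
small_sim <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- sim_config(n_subjects = 300, organs = c("brain", "heart"),
                      n_proteins_per_organ = 5, n_background_proteins = 20,
                      seed = 7)
    .fixture_cache$small <- simulate_cohort(cfg)
  }
  .fixture_cache$small
}

# Fixed sensible hyperparameters for tests that exercise selection or
# elimination without a tuning run.
fixed_hp <- function(nrounds = 150) {
  list(eta = 0.1, max_depth = 4, min_child_weight = 5, subsample = 0.9,
       colsample_bytree = 0.9, nrounds = nrounds)
}
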