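# Shared fixtures and memoised heavy fits. Everything is generated in code
# under fixed seeds; the expensive hierarchical fits are computed once per
# test run and reused across acceptance checks.

sb_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (!exists(key, envir = sb_cache)) assign(key, make(), envir = sb_cache)
  get(key, envir = sb_cache)
}

# first-of-block exclusion only: the generator produces no lapses, so the
# 2.5-SD cascade would only clip the tails of a well-specified von Mises
mark_first_trials <- function(trials) {
  trials |>
    dplyr::group_by(subject, block) |>
    dplyr::mutate(excluded = trial == min(trial)) |>
    dplyr::ungroup()
}

# 8 subjects (2 per range group) x 15 blocks from the stimulus-and-response
# generative model at default effect sizes
recovery_trials <- function() {
  cache_get("recovery_trials", function() {
    mark_first_trials(simulate_cohort(n_subjects = 8, n_blocks = 15, seed = 42))
  })
}

recovery_fit <- function(kind) {
  cache_get(paste0("fit_", kind), function() {
    fit_bias_model(recovery_trials(), bias_model(kind),
                   control = mcmc_control(), seed = 7)
  })
}

# medium cohort for bias-map structure checks (24 subjects, 6 per group)
map_trials <- function() {
  cache_get("map_trials", function() {
    mark_first_trials(simulate_cohort(n_subjects = 24, n_blocks = 4, seed = 99))
  })
}

# sampler metadata helper reused by the log-posterior cross-check
meta_for <- function(model, priors = hier_priors()) {
  serialbias:::sampler_meta(model, priors)
}
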