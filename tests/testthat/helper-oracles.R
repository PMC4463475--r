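# Shared fixtures and independent oracles used across the suite.

default_hp <- healthy_model_params()

make_series <- function(values, times = seq_along(values) - 1, id = "w") {
  biomarker_series(id, times, values)
}

# Monte-Carlo oracle for the marginal likelihood: integrate the personal
# baseline theta out by simulation. `mean_shift` is the deterministic
# trajectory component added to theta (0 for the flat model, the
# change-point ramp for one grid cell). Returns the log estimate and the
# standard error of the log.
mc_log_marginal <- function(series, hp, mean_shift = 0, n_draws = 1e6,
                            seed = 4242) {
  withr::with_seed(seed, {
    theta <- rnorm(n_draws, hp$mu0, sqrt(hp$tau2))
    ly <- log(series$values)
    shift <- rep_len(mean_shift, length(ly))
    tot <- rep(0, n_draws)
    for (j in seq_along(ly)) {
      tot <- tot + dnorm(ly[j], theta + shift[j], sqrt(hp$sigma2), log = TRUE)
    }
    m <- max(tot)
    w <- exp(tot - m)
    list(log_est = m + log(mean(w)),
         se_log = sd(w) / (sqrt(n_draws) * mean(w)))
  })
}

# deterministic stub samplers for protocol tests
const_marker_sampler <- function(value) function(t) value
const_scan_sampler <- function(status) function(t) status

# tiny deterministic trial cohort builder used by protocol/eval tests
small_cohort <- function(n_women = 50, years = 3, seed = 7, ...) {
  simulate_cohort(cohort_config(n_women = n_women, years_of_screening = years,
                                ...), seed = seed)
}
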