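# shared fixtures: small configs built in code, no stored data

small_config <- function(variant = "minimal_CLM", beta = 0.5, gamma = 1.5,
                         alpha = 0.5, L = 8, max_mcs = 50, seed = 7, ...) {
  simulation_config(variant, alpha = alpha, beta = beta, gamma = gamma,
                    L = L, max_mcs = max_mcs, seed = seed, ...)
}

# hand-rolled fraction series wrapped as a sim_timeseries for is_stationary()
fake_timeseries <- function(mcs, fractions) {
  structure(list(mcs = mcs, fractions = fractions,
                 config = list(relaxation_mcs = 0)),
            class = "sim_timeseries")
}
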