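# Small in-code fixtures shared across test files.

# Noiseless replicated time course generated from known kinetic parameters.
noiseless_tc <- function(params, times = seq(0, 14, by = 2), n_rep = 3,
                         time_unit = "hours") {
  vals <- predict_mrna(params, times)
  as_timecourse(
    data.frame(
      time = rep(times, n_rep),
      replicate = rep(seq_len(n_rep), each = length(times)),
      value = rep(vals, n_rep)
    ),
    time_unit = time_unit
  )
}

# Relative error helper.
rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# A tiny flow configuration for structural tests where fit quality does not
# matter, only contracts and determinism.
tiny_flow_config <- function(seed = 1, n_restarts = 2, top_k = 2) {
  flow_fit_config(
    n_restarts = n_restarts, top_k = top_k, n_sim_cells = 1000,
    ga_population = 8, ga_generations = 3, simplex_maxit = 40, seed = seed
  )
}
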