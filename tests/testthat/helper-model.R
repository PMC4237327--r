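# shared fixtures: a coarse grid keeps repeated model runs fast; the
# default-step grid is reserved for the checks that are about dt itself
fast_grid <- function(t_max = 100) simulation_grid(dt = 0.01, t_max = t_max)

default_mut <- function(n_min = 5, S = 30, u = 1e-7) {
  mutation_params(u = u, n_min = n_min, S = S)
}

default_pop <- function(k = 0.04, N0 = 1e5) population_params(N0 = N0, k = k)

quiet_fit <- function(...) suppressMessages(fit_incidence_model(...))

make_table <- function(k = 0.04, S = 30, n_min = 5, noise = "none",
                       sigma = 0.1, seed = NULL, grid = fast_grid()) {
  generate_synthetic_table(synthetic_table_spec(
    k = k, S = S, n_min = n_min, noise = noise, sigma = sigma,
    seed = seed, grid = grid))
}
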