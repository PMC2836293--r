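# small deterministic configs and fixtures shared across tests

tiny_config <- function(n_rural = 200, n_municipal = 600, seed = 11L, ...) {
  generator_config(n_rural = n_rural, n_municipal = n_municipal,
                   seed = seed, ...)
}

# deterministic generator limit: point-mass covariates, no noise
degenerate_config <- function(seed = 3L) {
  generator_config(
    n_rural = 20, n_municipal = 30, seed = seed,
    sigma = c(rural = 0, municipal = 0),
    beta_length = c(rural = 0, municipal = 0),
    beta_density = c(rural = 0, municipal = 0),
    length_dist = list(rural = dist_point(1600), municipal = dist_point(130)),
    density_dist = list(rural = dist_point(1.6), municipal = dist_point(30)))
}

# mean across replicate datasets of a per-dataset statistic
replicate_stat <- function(seeds, stat, ...) {
  vapply(seeds, function(s) {
    d <- generate_dataset(generator_config(seed = s, ...))
    stat(d)
  }, numeric(1))
}
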