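# Small in-code fixtures shared across test files.

# Noiseless (or low-noise) pooled dataset on a log-spaced dose grid.
make_pooled_data <- function(pIC50 = 6.2, Hill = 1.3, sigma = 0,
                             doses = 10^seq(-1.5, 1.5, length.out = 12),
                             seed = 1) {
  spec <- generator_spec(pIC50_fixed = pIC50, Hill_fixed = Hill,
                         sigma = sigma, n_experiments = 1,
                         concentrations = doses,
                         compound = "testdrug", channel = "testchan")
  generate_dataset(spec, seed = seed)
}

# Tiny multi-experiment dataset for structural tests.
make_hier_data <- function(ne = 3, seed = 2) {
  spec <- generator_spec(mu = 6, s = 0.15, alpha = 1, beta = 4,
                         sigma = 0.5, n_experiments = ne,
                         compound = "testdrug", channel = "testchan")
  generate_dataset(spec, seed = seed)
}

# Quadrature mass of the truncated observation density on [0, 100],
# split at the mean so narrow interior spikes are not missed.
trunc_mass <- function(f, sigma) {
  dens <- function(y) exp(hillbayes:::trunc_norm_loglik(y, f, sigma))
  lo <- integrate(dens, 0, f, rel.tol = 1e-10, subdivisions = 500L)$value
  hi <- integrate(dens, f, 100, rel.tol = 1e-10, subdivisions = 500L)$value
  lo + hi
}
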