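# Small deterministic fixtures shared across tests.

# Fixed 6 x 2 instrument matrix and exposure for exact-solution oracles.
tiny_fixture <- function() {
  G <- matrix(c(1.2, -0.4, 0.7, 2.1, -1.3, 0.2,
                0.5, 1.1, -0.9, 0.3, 0.8, -1.7), nrow = 6)
  colnames(G) <- c("snpA", "snpB")
  x <- c(0.9, 0.1, -0.5, 1.8, -1.1, -0.6)
  list(G = G, x = x)
}

# Small confounded dataset with a known quadratic effect, cheap to simulate.
small_settings <- function(n = 2000, m = 20, seed = 1, ...) {
  polymr_settings(n_samples = n, n_causal_snps = m, heritability = 0.5,
                  gwas_p_threshold = 1e-4, seed = seed, ...)
}

# Simulate, select instruments and fit in one step (small scale).
quick_fit <- function(settings, ...) {
  d <- simulate_dataset(settings)
  ivs <- select_instruments(d)
  polymr(d$exposure, d$outcome, d$genotypes[, ivs, drop = FALSE], ...)
}
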