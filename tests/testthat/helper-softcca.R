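# Shared fixture builders; everything is generated in code.

# standardized pure-noise pair
noise_pair <- function(n = 30, p = 12, q = 8, seed = 1) {
  set.seed(seed)
  scca_standardize(matrix(rnorm(n * p), n), matrix(rnorm(n * q), n))
}

# small strong-signal dataset with known structure
signal_pair <- function(n = 80, p = 120, q = 60, k_true = 2,
                        s1 = c(20, 10), s2 = c(12, 8),
                        latent_sd = c(3, 2), seed = 1) {
  sim <- scca_simulate(scca_design(n = n, p = p, q = q, k_true = k_true,
                                   support_sizes_1 = s1, support_sizes_2 = s2,
                                   latent_sd = latent_sd, seed = seed))
  list(pair = scca_standardize(sim$x1, sim$x2), sim = sim)
}

# centered orthonormal columns (Helmert contrasts), for exact-correlation
# constructions in the explained-variance tests
orthonormal_centered <- function(n, k) {
  h <- stats::contr.helmert(n)[, seq_len(k), drop = FALSE]
  apply(h, 2, function(v) v / sqrt(sum(v^2)))
}
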