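# Small in-code fixtures shared across test files.

make_covs <- function(n = 20, K = 3, seed = 1,
                      extents = seq(500, by = 500, length.out = K)) {
  set.seed(seed)
  site_covariates(matrix(runif(n * K), n, K), extents = extents)
}

# Covariates whose columns k1 and k2 are identical (for symmetry checks).
make_twin_covs <- function(n = 20, K = 2, seed = 1) {
  set.seed(seed)
  x <- runif(n)
  vals <- matrix(runif(n * K), n, K)
  vals[, 1] <- x
  vals[, 2] <- x
  site_covariates(vals, extents = seq(500, by = 500, length.out = K))
}

uniform_prior <- function(K, extents = NULL)
  model_prior(rep(1 / (K + 1), K + 1), extents = extents)
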