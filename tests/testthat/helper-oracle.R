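# Independent brute-force oracle: Gauss-Hermite integration of the
# coefficient prior out of the Gaussian likelihood. Deliberately does not
# touch the closed-form path it is used to check.

lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.gh_env <- new.env()
gh_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_env[[key]])) .gh_env[[key]] <- pracma::gaussHermite(n)
  .gh_env[[key]]
}

lml_quadrature <- function(y, X, sigma2, m0 = rep(0, ncol(X)),
                           V0 = diag(ncol(X)), n_nodes = 150) {
  X <- as.matrix(X)
  p <- ncol(X)
  L <- t(chol(V0))
  gh <- gh_nodes(n_nodes)
  u <- sqrt(2) * gh$x
  lw <- log(gh$w)
  if (p == 1L) {
    theta <- m0 + L[1, 1] * u                       # 1 x M grid
    mu <- outer(drop(X), theta)                     # n x M means
    ll <- colSums(dnorm(y, mu, sqrt(sigma2), log = TRUE))
    return(lse(lw - 0.5 * log(pi) + ll))
  }
  stopifnot(p == 2L)
  grid <- expand.grid(i = seq_along(u), j = seq_along(u))
  theta <- m0 + L %*% rbind(u[grid$i], u[grid$j])   # 2 x M grid
  mu <- X %*% theta                                 # n x M means
  ll <- colSums(dnorm(y, mu, sqrt(sigma2), log = TRUE))
  lse(lw[grid$i] + lw[grid$j] - log(pi) + ll)
}

# log density of a multivariate normal, used to re-derive full
# conditionals from first principles in sampler tests.
ldmvnorm <- function(x, mean, cov) {
  p <- length(x)
  R <- chol(cov)
  q <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(R))) + sum(q^2))
}

# Random small conjugate problem drawn from its own prior predictive.
random_problem <- function(n, K, seed, sigma2 = NULL) {
  set.seed(seed)
  sigma2 <- sigma2 %||% runif(1, 0.5, 2)
  covs <- site_covariates(matrix(runif(n * K), n, K),
                          extents = seq(500, by = 500, length.out = K))
  k_true <- sample(0:K, 1)
  X <- build_design(covs, k_true)
  theta <- rnorm(ncol(X))
  y <- drop(X %*% theta) + rnorm(n, sd = sqrt(sigma2))
  list(y = y, covs = covs, sigma2 = sigma2, k_true = k_true)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
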