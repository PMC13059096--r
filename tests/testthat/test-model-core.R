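# Closed-form marginal likelihoods, Bayes factors and exact posterior
# model probabilities for the known-variance conjugate Gaussian model.

test_that("design construction follows the model index convention", {
  covs <- make_covs(n = 10, K = 10)
  X0 <- build_design(covs, 0)
  expect_equal(dim(X0), c(10, 1))
  expect_true(all(X0 == 1))
  X5 <- build_design(covs, 5)
  expect_equal(dim(X5), c(10, 2))
  expect_equal(unname(X5[, 2]), unname(covs$values[, 5]))
  expect_equal(covs$extents[5], 2500)
  expect_error(build_design(covs, 11), "0\\.\\.10")
  expect_error(build_design(covs, -1), "extent_index")
})

test_that("one-observation marginal matches the hand closed form", {
  m <- gaussian_linear_model(y = 0, X = matrix(1), sigma2 = 1,
                             prior_mean = 0, prior_cov = matrix(1))
  # y ~ N(0, 1 + 1): log N(0; 0, 2) = -0.5 log(4 pi)
  expect_equal(log_marginal_likelihood(m), -0.5 * log(4 * pi),
               tolerance = 1e-12)
})

test_that("closed form agrees with brute-force quadrature on random toys", {
  for (s in 1:20) {
    pb <- random_problem(n = 5, K = 2, seed = 100 + s)
    k <- pb$k_true
    X <- build_design(pb$covs, k)
    m0 <- rep(0, ncol(X))
    V0 <- diag(ncol(X))
    m <- gaussian_linear_model(pb$y, X, pb$sigma2, m0, V0)
    a <- log_marginal_likelihood(m)
    b <- lml_quadrature(pb$y, X, pb$sigma2, m0, V0)
    expect_equal(a, b, tolerance = 1e-8)
  }
})

test_that("duplicating observations changes the marginal and the oracle tracks it", {
  pb <- random_problem(n = 4, K = 2, seed = 7)
  X <- build_design(pb$covs, 1)
  m1 <- gaussian_linear_model(pb$y, X, pb$sigma2)
  y2 <- rep(pb$y, 2)
  X2 <- rbind(X, X)
  m2 <- gaussian_linear_model(y2, X2, pb$sigma2)
  a2 <- log_marginal_likelihood(m2)
  expect_false(isTRUE(all.equal(log_marginal_likelihood(m1), a2)))
  expect_equal(a2, lml_quadrature(y2, X2, pb$sigma2), tolerance = 1e-8)
})

test_that("Bayes factors are antisymmetric and match the quadrature ratio", {
  pb <- random_problem(n = 5, K = 2, seed = 11)
  ma <- gaussian_linear_model(pb$y, build_design(pb$covs, 1), pb$sigma2)
  mb <- gaussian_linear_model(pb$y, build_design(pb$covs, 2), pb$sigma2)
  expect_equal(log_bayes_factor(ma, ma), 0)
  expect_equal(log_bayes_factor(ma, mb), -log_bayes_factor(mb, ma))
  expect_equal(log_bayes_factor(ma, mb),
               lml_quadrature(pb$y, build_design(pb$covs, 1), pb$sigma2) -
                 lml_quadrature(pb$y, build_design(pb$covs, 2), pb$sigma2),
               tolerance = 1e-7)
  mc <- gaussian_linear_model(pb$y[-1], build_design(
    site_covariates(pb$covs$values[-1, , drop = FALSE],
                    pb$covs$extents), 1), pb$sigma2)
  expect_error(log_bayes_factor(ma, mc), "same response")
})

test_that("exact posterior model probabilities normalise and respect the prior", {
  covs <- make_covs(n = 15, K = 3)
  set.seed(2)
  y <- rnorm(15)
  # all mass on the null model
  pr_null <- model_prior(c(1, 0, 0, 0))
  p <- exact_posterior_model_probs(y, covs, pr_null)
  expect_equal(as.numeric(p$prob), c(1, 0, 0, 0))
  expect_equal(p$method, "exact")
  expect_true(all(p$mc_error == 0))
  # identical designs with equal prior weight split the mass evenly
  twins <- make_twin_covs(n = 15)
  p2 <- exact_posterior_model_probs(y, twins, model_prior(c(0, 0.5, 0.5)))
  expect_equal(as.numeric(p2$prob), c(0, 0.5, 0.5), tolerance = 1e-12)
  # sums to one for random priors, zero weight stays exactly zero
  for (s in 1:10) {
    set.seed(s)
    w <- runif(4)
    w[sample(4, 1)] <- 0
    pr <- model_prior(w / sum(w))
    pp <- exact_posterior_model_probs(y, covs, pr)
    expect_equal(sum(pp$prob), 1, tolerance = 1e-10)
    expect_equal(as.numeric(pp$prob)[as.numeric(pr) == 0], 0)
  }
  expect_error(exact_posterior_model_probs(y, covs, rep(0, 4)), "zero")
})

test_that("raising a model's prior weight never lowers its posterior", {
  covs <- make_covs(n = 12, K = 3, seed = 5)
  set.seed(6)
  y <- rnorm(12)
  pr <- uniform_prior(3)
  base <- exact_posterior_model_probs(y, covs, pr)
  for (k in 0:3) {
    bumped <- bump_weight(pr, k, 2.5)
    pb <- exact_posterior_model_probs(y, covs, bumped)
    expect_gte(as.numeric(pb$prob)[k + 1] + 1e-12,
               as.numeric(base$prob)[k + 1])
  }
})

test_that("a strong mid-grid signal drives the null probability to zero", {
  covs <- simulate_extent_covariates(100, seed = 42)
  y <- simulate_response(covs, 2500, beta0 = 1, beta = 1.8, sigma = 1,
                         seed = 43)
  p <- exact_posterior_model_probs(y, covs, uniform_prior(10), sigma2 = 1)
  probs <- as.numeric(p$prob)
  expect_lt(probs[1], 0.05)
  # with inter-extent correlations of 0.85-0.99 the extent mass is spread
  # across neighbours of the true 2500 m scale; its centre stays mid-grid
  mean_extent <- sum(probs[-1] * covs$extents) / sum(probs[-1])
  expect_gt(mean_extent, 2000)
  expect_lt(mean_extent, 4000)
  top <- which.max(probs[-1])
  expect_gte(covs$extents[top], 1500)
  expect_lte(covs$extents[top], 4000)
})

test_that("unknown-variance marginal matches integrating the known-variance form", {
  pb <- random_problem(n = 6, K = 2, seed = 21, sigma2 = 1)
  X <- build_design(pb$covs, 1)
  a0 <- 2
  b0 <- 1.5
  got <- log_marginal_likelihood_nig(pb$y, X, a0 = a0, b0 = b0)
  # oracle: integrate p(y | sigma2) against the inverse-gamma prior
  integrand <- function(s2) {
    vapply(s2, function(v)
      exp(log_marginal_likelihood(gaussian_linear_model(
        pb$y, X, v, prior_cov = v * diag(2))) +
            a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(v) - b0 / v),
      numeric(1))
  }
  want <- log(integrate(integrand, 0, Inf, rel.tol = 1e-10)$value)
  expect_equal(got, want, tolerance = 1e-6)
})
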