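# The Gibbs-formulated reversible-jump estimator: per-model conjugate
# sampling, pseudo-priors, the indicator full conditional, and the
# Rao-Blackwellised probability estimates.

test_that("per-model draws match the analytic conjugate posterior", {
  pb <- random_problem(n = 5, K = 2, seed = 31, sigma2 = 1.3)
  X <- build_design(pb$covs, 1)
  n_draws <- 1e5
  d <- sample_model_posterior(pb$y, pb$covs, 1, sigma2 = pb$sigma2,
                              n_iter = n_draws, seed = 99)
  V0inv <- diag(2)
  prec <- V0inv + crossprod(X) / pb$sigma2
  Vn <- solve(prec)
  mn <- drop(Vn %*% (crossprod(X, pb$y) / pb$sigma2))
  for (j in 1:2) {
    mcse <- sqrt(Vn[j, j] / n_draws)
    expect_lt(abs(mean(d[, j]) - mn[j]), 3 * mcse)
    expect_equal(var(d[, j]), Vn[j, j], tolerance = 0.05)
  }
  expect_equal(cov(d)[1, 2], Vn[1, 2], tolerance = 0.05)
  # reproducibility from seed, without clobbering the global stream
  d2 <- sample_model_posterior(pb$y, pb$covs, 1, sigma2 = pb$sigma2,
                               n_iter = 100, seed = 7)
  d3 <- sample_model_posterior(pb$y, pb$covs, 1, sigma2 = pb$sigma2,
                               n_iter = 100, seed = 7)
  expect_identical(d2, d3)
})

test_that("degenerate limits of the within-model sampler behave", {
  covs <- make_covs(n = 8, K = 2, seed = 3)
  y <- rnorm(8)
  # near-degenerate prior pins the draws at the prior mean
  tight <- coef_prior(mean = c(2, -1), cov = diag(2) * 1e-12)
  d <- sample_model_posterior(y, covs, 1, coef_prior = tight,
                              n_iter = 500, seed = 1)
  expect_equal(unname(colMeans(d)), c(2, -1), tolerance = 1e-4)
  # no observations: draws come from the prior
  covs0 <- site_covariates(matrix(numeric(0), 0, 2), extents = c(500, 1000))
  d0 <- sample_model_posterior(numeric(0), covs0, 1, n_iter = 2e4,
                               seed = 2)
  expect_equal(unname(colMeans(d0)), c(0, 0), tolerance = 0.03)
  expect_equal(unname(apply(d0, 2, sd)), c(1, 1), tolerance = 0.03)
})

test_that("pseudo-priors moment-match the active-model slope draws", {
  set.seed(4)
  draws <- list(cbind(rnorm(1000), rnorm(1000, 2, 0.5)),
                cbind(rnorm(1000), rnorm(1000, -1, 2)))
  ps <- fit_pseudo_priors(draws)
  expect_equal(ps$location, c(mean(draws[[1]][, 2]), mean(draws[[2]][, 2])))
  expect_equal(ps$scale, c(sd(draws[[1]][, 2]), sd(draws[[2]][, 2])))
  degen <- list(cbind(rnorm(10), rep(1, 10)))
  expect_error(fit_pseudo_priors(degen), "n_iter")
})

test_that("indicator full conditional matches a from-first-principles computation", {
  pb <- random_problem(n = 10, K = 3, seed = 41, sigma2 = 0.8)
  prior <- model_prior(c(0.4, 0.3, 0.2, 0.1))
  pseudo <- structure(list(location = c(0.5, -0.2, 1),
                           scale = c(0.4, 0.7, 1.2)),
                      class = "pseudo_prior_set")
  cp <- coef_prior(mean = c(0.1, -0.3),
                   cov = matrix(c(1.2, 0.3, 0.3, 0.9), 2))
  set.seed(5)
  for (rep in 1:5) {
    state <- list(beta0 = rnorm(1), betas = rnorm(3), model_index = 1)
    got <- model_full_conditional(state, pb$y, pb$covs, prior, pseudo,
                                  sigma2 = pb$sigma2, coef_prior = cp)
    logw <- vapply(0:3, function(m) {
      mu <- if (m == 0) rep(state$beta0, 10)
      else state$beta0 + state$betas[m] * pb$covs$values[, m]
      ll <- sum(dnorm(pb$y, mu, sqrt(pb$sigma2), log = TRUE))
      lp <- if (m == 0) dnorm(state$beta0, cp$mean[1], sqrt(cp$cov[1, 1]),
                              log = TRUE)
      else ldmvnorm(c(state$beta0, state$betas[m]), cp$mean, cp$cov)
      inactive <- setdiff(1:3, m)
      lps <- sum(dnorm(state$betas[inactive], pseudo$location[inactive],
                       pseudo$scale[inactive], log = TRUE))
      log(as.numeric(prior)[m + 1]) + ll + lp + lps
    }, numeric(1))
    want <- exp(logw - lse(logw))
    expect_equal(got, want / sum(want), tolerance = 1e-10)
  }
})

test_that("symmetric twin models split the full conditional evenly", {
  twins <- make_twin_covs(n = 12, seed = 6)
  y <- rnorm(12)
  pseudo <- structure(list(location = c(0.3, 0.3), scale = c(0.5, 0.5)),
                      class = "pseudo_prior_set")
  for (rep in 1:3) {
    state <- list(beta0 = rnorm(1), betas = rep(rnorm(1), 2),
                  model_index = 1)
    p <- model_full_conditional(state, y, twins, model_prior(c(0, .5, .5)),
                                pseudo, sigma2 = 1)
    expect_equal(p[2], p[3], tolerance = 1e-12)
  }
})

test_that("averaging the full conditional over exact palette draws recovers the exact posterior", {
  pb <- random_problem(n = 30, K = 2, seed = 51, sigma2 = 1)
  prior <- uniform_prior(2)
  exact <- as.numeric(exact_posterior_model_probs(pb$y, pb$covs, prior,
                                                  1)$prob)
  draws <- lapply(0:2, function(k)
    sample_model_posterior(pb$y, pb$covs, k, sigma2 = 1, n_iter = 4000,
                           seed = 60 + k))
  pseudo <- fit_pseudo_priors(draws[-1])
  set.seed(8)
  acc <- numeric(3)
  n_mc <- 4000
  for (t in seq_len(n_mc)) {
    k <- sample(0:2, 1, prob = exact)
    beta <- rnorm(2, pseudo$location, pseudo$scale)
    b0 <- draws[[k + 1]][t, 1]
    if (k >= 1) beta[k] <- draws[[k + 1]][t, 2]
    acc <- acc + model_full_conditional(
      list(beta0 = b0, betas = beta, model_index = k),
      pb$y, pb$covs, prior, pseudo, sigma2 = 1)
  }
  expect_equal(acc / n_mc, exact, tolerance = 0.02)
})

test_that("run_infr honours degenerate priors exactly", {
  covs <- make_covs(n = 10, K = 3, seed = 7)
  y <- rnorm(10)
  p <- run_infr(y, covs, model_prior(c(1, 0, 0, 0)), sigma2 = 1,
                config = rj_config(n_iter = 200, n_chains = 2, seed = 1))
  expect_equal(as.numeric(p$prob), c(1, 0, 0, 0))
  expect_equal(p$method, "infR")
})

test_that("run_infr converges to the exact posterior on a toy problem", {
  pb <- random_problem(n = 40, K = 3, seed = 61, sigma2 = 1)
  prior <- uniform_prior(3)
  exact <- as.numeric(exact_posterior_model_probs(pb$y, pb$covs, prior,
                                                  1)$prob)
  est <- suppressWarnings(
    run_infr(pb$y, pb$covs, prior, sigma2 = 1,
             config = rj_config(n_iter = 4000, n_chains = 3, seed = 17)))
  expect_equal(sum(est$prob), 1, tolerance = 1e-10)
  expect_lt(max(abs(as.numeric(est$prob) - exact)), 0.01)
})

test_that("independent seeds agree within their Monte Carlo error", {
  pb <- random_problem(n = 40, K = 3, seed = 71, sigma2 = 1)
  prior <- uniform_prior(3)
  e1 <- run_infr(pb$y, pb$covs, prior, sigma2 = 1,
                 config = rj_config(n_iter = 3000, seed = 1))
  e2 <- run_infr(pb$y, pb$covs, prior, sigma2 = 1,
                 config = rj_config(n_iter = 3000, seed = 2))
  tol <- 3 * pmax(e1$mc_error, e2$mc_error) + 0.005
  expect_true(all(abs(as.numeric(e1$prob) - as.numeric(e2$prob)) < tol))
  # same seed is bit-reproducible
  e3 <- run_infr(pb$y, pb$covs, prior, sigma2 = 1,
                 config = rj_config(n_iter = 3000, seed = 1))
  expect_identical(as.numeric(e1$prob), as.numeric(e3$prob))
})

test_that("relabelling extents permutes the probabilities within Monte Carlo error", {
  pb <- random_problem(n = 50, K = 3, seed = 81, sigma2 = 1)
  w <- c(0.4, 0.3, 0.2, 0.1)
  est <- run_infr(pb$y, pb$covs, model_prior(w), sigma2 = 1,
                  config = rj_config(n_iter = 4000, seed = 5))
  perm <- c(3, 1, 2)  # permute the extent labels (null stays put)
  covs_p <- site_covariates(pb$covs$values[, perm],
                            extents = pb$covs$extents)
  est_p <- run_infr(pb$y, covs_p, model_prior(c(w[1], w[perm + 1])),
                    sigma2 = 1, config = rj_config(n_iter = 4000, seed = 5))
  back <- c(1, order(perm) + 1)
  expect_lt(max(abs(as.numeric(est_p$prob)[back] -
                      as.numeric(est$prob))), 0.02)
})

test_that("grossly mis-scaled pseudo-priors inflate the Monte Carlo error", {
  # same problem, pseudo-prior scale x100: the RB average from palettes
  # drawn with the bad pseudo-priors is further from the exact answer.
  pb <- random_problem(n = 30, K = 2, seed = 91, sigma2 = 1)
  prior <- uniform_prior(2)
  exact <- as.numeric(exact_posterior_model_probs(pb$y, pb$covs, prior,
                                                  1)$prob)
  draws <- lapply(0:2, function(k)
    sample_model_posterior(pb$y, pb$covs, k, sigma2 = 1, n_iter = 2000,
                           seed = 70 + k))
  good <- fit_pseudo_priors(draws[-1])
  bad <- structure(list(location = good$location,
                        scale = good$scale * 100),
                   class = "pseudo_prior_set")
  err <- function(pseudo) {
    set.seed(12)
    acc <- numeric(3)
    for (t in 1:800) {
      k <- sample(0:2, 1, prob = exact)
      beta <- rnorm(2, pseudo$location, pseudo$scale)
      if (k >= 1) beta[k] <- draws[[k + 1]][t, 2]
      acc <- acc + model_full_conditional(
        list(beta0 = draws[[k + 1]][t, 1], betas = beta, model_index = k),
        pb$y, pb$covs, prior, pseudo, sigma2 = 1)
    }
    max(abs(acc / 800 - exact))
  }
  expect_gt(err(bad), err(good))
})
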