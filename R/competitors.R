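# Reconstructions of the two latent-indicator scale-selection competitors,
# restricted to the known-variance Gaussian setting so that differences
# from the informed-prior estimator reflect model-space structure only.
# Both methods place a discrete-uniform prior over the K extents and have
# no way to put mass on the no-association model, so their returned
# probability vector always assigns 0 to the null model.

#' BLISS-style latent indicator scale selection
#'
#' Collapsed Gibbs reconstruction: with the coefficients integrated out,
#' the scale indicator's full conditional is categorical with mass
#' proportional to `prior(k) * p(y | M_k)` over the `K` extent models
#' (discrete-uniform prior, null model excluded by construction). That
#' full conditional does not depend on the rest of the state, so its
#' Rao-Blackwell average is available exactly and the function returns it
#' with zero Monte Carlo error: the restricted-space exact posterior.
#'
#' @inheritParams exact_posterior_model_probs
#' @param config an [rj_config()]; accepted for interface uniformity (the
#'   collapsed estimate does not need iterations).
#' @return a [posterior_model_probs()] with `method = "BLISS"` and
#'   `prob[1] = 0`.
#' @export
run_bliss <- function(y, covariates, sigma2 = 1, coef_prior = NULL,
                      config = rj_config()) {
  K <- n_extents(covariates)
  if (K < 2) stop("BLISS needs at least 2 candidate extents", call. = FALSE)
  y <- as.numeric(y)
  cp <- coef_prior %||% coef_prior()
  lml <- all_log_marginals(y, covariates, cp, sigma2)[-1L]
  logw <- -log(K) + lml
  p <- exp(logw - logsumexp(logw))
  posterior_model_probs(c(0, p / sum(p)), mc_error = numeric(K + 1L),
                        method = "BLISS", extents = covariates$extents)
}

#' SS-style scale selection with adjacent-extent Metropolis moves
#'
#' Metropolis-within-Gibbs reconstruction of automated scale selection:
#' the state is `(delta, intercept, slope)` with a single slope shared
#' across scales. Given `delta`, the coefficients are drawn from the
#' conjugate posterior of model `delta`; `delta` is then updated by a
#' Metropolis step that proposes moving to an adjacent extent index
#' (`+1` or `-1` with equal probability, proposals outside `1..K`
#' rejected). The stationary distribution over extents is the exact
#' restricted posterior, but the local proposal mixes slowly at the ends
#' of the grid, which is what produces the method's characteristic edge
#' effects at the smallest and largest extents. Probabilities are
#' estimated by post-burn-in visit frequencies averaged over chains.
#'
#' @inheritParams exact_posterior_model_probs
#' @param config an [rj_config()] controlling iterations, chains and seed.
#' @return a [posterior_model_probs()] with `method = "SS"` and
#'   `prob[1] = 0`.
#' @export
run_ss <- function(y, covariates, sigma2 = 1, coef_prior = NULL,
                   config = rj_config()) {
  K <- n_extents(covariates)
  if (K < 2) stop("SS needs at least 2 candidate extents", call. = FALSE)
  y <- as.numeric(y)
  cp <- coef_prior %||% coef_prior()
  mom <- lapply(seq_len(K), function(k)
    posterior_moments(y, build_design(covariates, k),
                      model_coef_prior(cp, k), sigma2))
  st <- palette_stats(y, covariates)
  n_iter <- config$n_iter
  burn <- floor(config$burn_frac * n_iter)
  seeds <- substream_seeds(config$seed, config$n_chains)
  freq <- matrix(NA_real_, nrow = config$n_chains, ncol = K)
  rss_at <- function(b0, b1, k)
    st$Syy - 2 * b0 * st$Sy + st$n * b0^2 - 2 * b1 * st$Sxy[k] +
      2 * b0 * b1 * st$Sx[k] + b1^2 * st$Sxx[k]
  for (c in seq_len(config$n_chains)) {
    freq[c, ] <- with_seed(seeds[[c]], {
      visits <- numeric(K)
      delta <- ceiling(K / 2)
      for (t in seq_len(n_iter)) {
        m <- mom[[delta]]
        th <- m$mean + drop(crossprod(m$chol, rnorm(2)))
        prop <- delta + sample(c(-1L, 1L), 1L)
        if (prop >= 1L && prop <= K) {
          logr <- (rss_at(th[1], th[2], delta) -
                     rss_at(th[1], th[2], prop)) / (2 * sigma2)
          if (log(runif(1)) < logr) delta <- prop
        }
        if (t > burn) visits[delta] <- visits[delta] + 1
      }
      visits / (n_iter - burn)
    })
  }
  prob <- colMeans(freq)
  mc <- if (config$n_chains >= 2L) apply(freq, 2, sd) else numeric(K)
  posterior_model_probs(c(0, prob), mc_error = c(0, mc), method = "SS",
                        extents = covariates$extents)
}

#' Exact posterior over the extent models only
#'
#' Helper computing the restricted-space truth the competitors target:
#' the null model removed and the prior renormalised over the `K` extents.
#'
#' @inheritParams exact_posterior_model_probs
#' @param prior optional [model_prior()]; its extent weights are
#'   renormalised (default: uniform over extents).
#' @return a [posterior_model_probs()] with `prob[1] = 0`.
#' @export
exact_restricted_posterior <- function(y, covariates, sigma2 = 1,
                                       coef_prior = NULL, prior = NULL) {
  K <- n_extents(covariates)
  w <- if (is.null(prior)) rep(1 / K, K) else {
    ew <- as.numeric(prior)[-1L]
    if (sum(ew) == 0)
      stop("prior puts no mass on any extent", call. = FALSE)
    ew / sum(ew)
  }
  cp <- coef_prior %||% coef_prior()
  lml <- all_log_marginals(as.numeric(y), covariates, cp, sigma2)[-1L]
  logw <- log(w) + lml
  p <- exp(logw - logsumexp(logw))
  p[w == 0] <- 0
  posterior_model_probs(c(0, p / sum(p)), method = "exact",
                        extents = covariates$extents)
}
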