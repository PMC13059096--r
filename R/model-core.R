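# Exact Bayesian computation for the known-variance Gaussian linear model:
# design construction, closed-form marginal likelihoods, Bayes factors and
# exact posterior model probabilities.

#' Gaussian coefficient prior
#'
#' Multivariate normal prior on `(intercept, slope)`. The default is the
#' weakly informative independent standard normal used throughout the
#' package; the null model uses only the intercept component.
#'
#' @param mean length-2 prior mean (intercept, slope).
#' @param cov 2 x 2 symmetric positive-definite prior covariance.
#' @return list with elements `mean` and `cov`, class `"coef_prior"`.
#' @export
coef_prior <- function(mean = c(0, 0), cov = diag(2)) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  if (length(mean) != 2L || !identical(dim(cov), c(2L, 2L)))
    stop("'mean' must have length 2 and 'cov' must be 2 x 2", call. = FALSE)
  if (max(abs(cov - t(cov))) > 1e-10)
    stop("'cov' must be symmetric", call. = FALSE)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("'cov' must be positive definite", call. = FALSE)
  structure(list(mean = mean, cov = cov), class = "coef_prior")
}

# Restrict a coef_prior to the parameters of model k (k = 0: intercept only).
model_coef_prior <- function(cp, k) {
  if (k == 0L)
    list(mean = cp$mean[1L], cov = cp$cov[1L, 1L, drop = FALSE])
  else
    list(mean = cp$mean, cov = cp$cov)
}

#' Known-variance Gaussian linear model with Gaussian coefficient prior
#'
#' Bundles the ingredients of the conjugate model
#' `y ~ N(X theta, sigma2 I)`, `theta ~ N(m0, V0)` with `sigma2` known,
#' for which the marginal likelihood of `y` is available in closed form.
#'
#' @param y response vector.
#' @param X design matrix with `length(y)` rows.
#' @param sigma2 known error variance, positive.
#' @param prior_mean prior mean `m0` (length `ncol(X)`).
#' @param prior_cov prior covariance `V0` (symmetric positive definite).
#' @return object of class `"gaussian_linear_model"`.
#' @seealso [log_marginal_likelihood()], [log_bayes_factor()]
#' @export
gaussian_linear_model <- function(y, X, sigma2,
                                  prior_mean = rep(0, ncol(X)),
                                  prior_cov = diag(ncol(X))) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (nrow(X) != length(y))
    stop("'X' must have one row per observation", call. = FALSE)
  stopifnot_scalar(sigma2, "sigma2", positive = TRUE)
  p <- ncol(X)
  prior_mean <- as.numeric(prior_mean)
  prior_cov <- as.matrix(prior_cov)
  if (length(prior_mean) != p || !identical(dim(prior_cov), c(p, p) + 0L))
    stop("prior dimensions must match ncol(X)", call. = FALSE)
  if (max(abs(prior_cov - t(prior_cov))) > 1e-10)
    stop("'prior_cov' must be symmetric", call. = FALSE)
  ev <- eigen(prior_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("'prior_cov' must be positive definite", call. = FALSE)
  structure(list(y = y, X = X, sigma2 = sigma2, prior_mean = prior_mean,
                 prior_cov = prior_cov),
            class = "gaussian_linear_model")
}

#' Design matrix for one candidate model
#'
#' Model 0 (no association) is intercept-only; model `k >= 1` pairs the
#' intercept with the covariate at the `k`-th extent, untransformed.
#'
#' @param covariates a [site_covariates()] object.
#' @param extent_index integer in `0 ... K`.
#' @return an `n x 1` or `n x 2` design matrix.
#' @export
build_design <- function(covariates, extent_index) {
  K <- n_extents(covariates)
  if (!is.numeric(extent_index) || length(extent_index) != 1L ||
      extent_index != round(extent_index) || extent_index < 0 ||
      extent_index > K)
    stop(sprintf(
      "'extent_index' must be an integer in 0..%d (0 = no-association model); got %s",
      K, format(extent_index)), call. = FALSE)
  n <- nrow(covariates$values)
  if (extent_index == 0)
    matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "intercept"))
  else
    cbind(intercept = rep(1, n),
          covariates$values[, extent_index, drop = TRUE])
}

#' Closed-form log marginal likelihood (known variance)
#'
#' Integrating the Gaussian coefficient prior out of the Gaussian likelihood
#' leaves `y ~ N(X m0, sigma2 I + X V0 X')`; the function evaluates that
#' multivariate normal log density through a Cholesky factorisation.
#'
#' @param model a [gaussian_linear_model()].
#' @return the scalar `log p(y | model)`.
#' @export
log_marginal_likelihood <- function(model) {
  if (!inherits(model, "gaussian_linear_model"))
    stop("'model' must be a gaussian_linear_model", call. = FALSE)
  y <- model$y
  X <- model$X
  n <- length(y)
  if (n == 0L) return(0)
  S <- model$sigma2 * diag(n) + X %*% model$prior_cov %*% t(X)
  S <- (S + t(S)) / 2
  R <- tryCatch(chol(S), error = function(e)
    stop("marginal covariance is not positive definite", call. = FALSE))
  r <- y - drop(X %*% model$prior_mean)
  q <- backsolve(R, r, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(q^2))
}

#' Log marginal likelihood with unknown variance (experimental)
#'
#' Normal-inverse-gamma conjugate marginal: `sigma2 ~ IG(a0, b0)`,
#' `theta | sigma2 ~ N(m0, sigma2 V0)`, giving a multivariate-t marginal
#' for `y`. Provided as an experimental extension; the estimators in this
#' package otherwise treat `sigma2` as known.
#'
#' @param y response vector.
#' @param X design matrix.
#' @param prior_mean,prior_cov coefficient prior `m0`, `V0`.
#' @param a0,b0 inverse-gamma shape and rate (default 0.01, 0.01).
#' @return scalar log marginal density of `y`.
#' @export
log_marginal_likelihood_nig <- function(y, X,
                                        prior_mean = rep(0, ncol(X)),
                                        prior_cov = diag(ncol(X)),
                                        a0 = 0.01, b0 = 0.01) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot_scalar(a0, "a0", positive = TRUE)
  stopifnot_scalar(b0, "b0", positive = TRUE)
  if (n == 0L) return(0)
  nu <- 2 * a0
  S <- (b0 / a0) * (diag(n) + X %*% prior_cov %*% t(X))
  S <- (S + t(S)) / 2
  R <- chol(S)
  r <- y - drop(X %*% as.numeric(prior_mean))
  q <- sum(backsolve(R, r, transpose = TRUE)^2)
  lgamma((nu + n) / 2) - lgamma(nu / 2) - (n / 2) * log(nu * pi) -
    sum(log(diag(R))) - ((nu + n) / 2) * log1p(q / nu)
}

#' Log Bayes factor between two models sharing the same response
#'
#' @param model_a,model_b [gaussian_linear_model()] objects fitted to the
#'   same response vector.
#' @return `log_marginal_likelihood(model_a) - log_marginal_likelihood(model_b)`.
#' @export
log_bayes_factor <- function(model_a, model_b) {
  if (!inherits(model_a, "gaussian_linear_model") ||
      !inherits(model_b, "gaussian_linear_model"))
    stop("both arguments must be gaussian_linear_model objects",
         call. = FALSE)
  if (length(model_a$y) != length(model_b$y) ||
      any(model_a$y != model_b$y))
    stop("models must share the same response vector", call. = FALSE)
  log_marginal_likelihood(model_a) - log_marginal_likelihood(model_b)
}

# Log marginal likelihood of every model 0..K for one covariate table.
all_log_marginals <- function(y, covariates, coef_prior, sigma2,
                              standardize = FALSE) {
  K <- n_extents(covariates)
  vals <- covariates$values
  if (standardize) {
    vals <- scale(vals)
    covariates$values <- matrix(pmin(pmax(vals, -Inf), Inf),
                                nrow = nrow(vals))
  }
  vapply(0:K, function(k) {
    X <- if (k == 0)
      matrix(1, nrow = length(y), ncol = 1)
    else
      cbind(1, if (standardize) vals[, k] else covariates$values[, k])
    mp <- model_coef_prior(coef_prior, k)
    log_marginal_likelihood(gaussian_linear_model(
      y, X, sigma2, prior_mean = mp$mean, prior_cov = mp$cov))
  }, numeric(1))
}

#' Exact posterior model probabilities (known variance)
#'
#' Combines the discrete model prior with the closed-form marginal
#' likelihood of every candidate model and normalises with a log-sum-exp
#' guard: `Pr(M_k | y)` is proportional to `Pr(M_k) p(y | M_k)`. Because
#' consecutive extents are typically correlated above 0.95 the marginals are
#' near-ties, so all work is done in log space.
#'
#' @param y response vector measured at the site centers.
#' @param covariates a [site_covariates()] object with `K` extents.
#' @param prior a [model_prior()] with `K + 1` weights.
#' @param sigma2 known error variance.
#' @param coef_prior a [coef_prior()]; defaults to independent standard
#'   normals on intercept and slope.
#' @param standardize center and scale the covariate columns before
#'   building designs. Off by default: proportions are used directly.
#' @return a [posterior_model_probs()] with `method = "exact"` and zero
#'   Monte Carlo error.
#' @examples
#' covs <- simulate_extent_covariates(50, seed = 1)
#' y <- simulate_response(covs, 2500, beta0 = 1, beta = 1.8, sigma = 1,
#'                        seed = 2)
#' pr <- point_mass_prior(0.5, rep(1, 10), extents = covs$extents)
#' exact_posterior_model_probs(y, covs, pr, sigma2 = 1)
#' @export
exact_posterior_model_probs <- function(y, covariates, prior, sigma2 = 1,
                                        coef_prior = NULL,
                                        standardize = FALSE) {
  y <- as.numeric(y)
  if (length(y) != nrow(covariates$values))
    stop("'y' must have one value per site", call. = FALSE)
  K <- n_extents(covariates)
  if (length(prior) != K + 1L)
    stop(sprintf("prior has %d weights but %d models are defined",
                 length(prior), K + 1L), call. = FALSE)
  if (all(prior == 0)) stop("all prior weights are zero", call. = FALSE)
  cp <- coef_prior %||% coef_prior()
  if (standardize) {
    sds <- apply(covariates$values, 2, sd)
    if (any(sds == 0))
      stop("cannot standardize a constant covariate column", call. = FALSE)
    z <- scale(covariates$values)
    lml <- vapply(0:K, function(k) {
      X <- if (k == 0) matrix(1, length(y), 1) else cbind(1, z[, k])
      mp <- model_coef_prior(cp, k)
      log_marginal_likelihood(gaussian_linear_model(
        y, X, sigma2, prior_mean = mp$mean, prior_cov = mp$cov))
    }, numeric(1))
  } else {
    lml <- all_log_marginals(y, covariates, cp, sigma2)
  }
  logw <- log(as.numeric(prior)) + lml
  probs <- exp(logw - logsumexp(logw))
  probs[as.numeric(prior) == 0] <- 0
  probs <- probs / sum(probs)
  posterior_model_probs(probs, mc_error = numeric(K + 1L),
                        method = "exact", extents = covariates$extents)
}
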