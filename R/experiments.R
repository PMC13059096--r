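# Method-comparison simulation against the analytic truth, and univariate
# screening of several covariates.

#' Mean absolute deviation and root mean square error
#'
#' Pooled over every (replication, model) cell: `mad` is the mean of
#' `|estimate - truth|`, `rmse` the square root of the mean squared
#' difference.
#'
#' @param estimates,truths numeric matrices (replications x models) of the
#'   same shape.
#' @return named numeric vector `c(mad, rmse)`.
#' @export
mad_rmse <- function(estimates, truths) {
  estimates <- as.matrix(estimates)
  truths <- as.matrix(truths)
  if (!identical(dim(estimates), dim(truths)))
    stop("'estimates' and 'truths' must have the same shape", call. = FALSE)
  d <- estimates - truths
  c(mad = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Method-comparison simulation with analytic truths
#'
#' For each association scenario and replication: simulates a response from
#' the true model (covariates drawn once and shared by all replications),
#' computes the exact posterior over the full model space (uniform prior
#' over the `K + 1` models, the no-association model included), runs each
#' requested estimator on the same data, and aggregates the per-cell
#' differences into per-scenario and pooled MAD / rMSE. Competitor
#' estimates are compared against the same full-space truth, which is what
#' exposes their bias when the no-association model carries posterior
#' mass.
#'
#' @param config a [simulation_config()].
#' @param methods subset of `c("infR", "SS", "BLISS")`.
#' @param rj_config an [rj_config()] used by the sampling-based methods.
#' @return object of class `"scale_simulation"`: `summary` (data frame of
#'   method x scenario and pooled MAD / rMSE), `diffs` (per method and
#'   scenario, replications x models matrices of estimate - truth),
#'   `truths`, `covariates`, `config`.
#' @export
run_scale_simulation <- function(config = simulation_config(),
                                 methods = c("infR", "SS", "BLISS"),
                                 rj_config = NULL) {
  rj_config <- rj_config %||% scalesel::rj_config()
  methods <- unique(methods)
  bad <- setdiff(methods, c("infR", "SS", "BLISS"))
  if (length(bad))
    stop("unknown method label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  K <- length(config$extents)
  n_scen <- length(config$beta_true)
  seeds <- substream_seeds(config$seed,
                           1L + n_scen * config$n_reps * 2L)
  covs <- simulate_extent_covariates(config$n_sites, config$extents,
                                     seed = seeds[[1L]])
  prior <- model_prior(rep(1 / (K + 1), K + 1), extents = config$extents)
  sigma2 <- config$sigma^2
  scen_names <- names(config$beta_true)
  diffs <- lapply(setNames(methods, methods), function(m)
    lapply(setNames(scen_names, scen_names), function(s)
      matrix(NA_real_, config$n_reps, K + 1L)))
  truths <- lapply(setNames(scen_names, scen_names), function(s)
    matrix(NA_real_, config$n_reps, K + 1L))
  si <- 1L
  for (s in seq_len(n_scen)) {
    beta <- config$beta_true[s]
    for (r in seq_len(config$n_reps)) {
      y <- simulate_response(covs, config$target_extent, config$beta0,
                             beta, config$sigma, seed = seeds[[1L + si]])
      truth <- exact_posterior_model_probs(y, covs, prior, sigma2)
      truths[[s]][r, ] <- as.numeric(truth$prob)
      rj <- rj_config
      rj$seed <- seeds[[1L + si + 1L]]
      for (m in methods) {
        est <- switch(m,
                      infR = run_infr(y, covs, prior, sigma2,
                                      config = rj),
                      SS = run_ss(y, covs, sigma2, config = rj),
                      BLISS = run_bliss(y, covs, sigma2, config = rj))
        diffs[[m]][[s]][r, ] <- as.numeric(est$prob) - truths[[s]][r, ]
      }
      si <- si + 2L
    }
  }
  rows <- list()
  for (m in methods) {
    for (s in scen_names) {
      e <- mad_rmse(diffs[[m]][[s]], 0 * diffs[[m]][[s]])
      rows[[length(rows) + 1L]] <-
        data.frame(method = m, scenario = s, mad = e[["mad"]],
                   rmse = e[["rmse"]])
    }
    pooled <- do.call(rbind, diffs[[m]])
    e <- mad_rmse(pooled, 0 * pooled)
    rows[[length(rows) + 1L]] <-
      data.frame(method = m, scenario = "pooled", mad = e[["mad"]],
                 rmse = e[["rmse"]])
  }
  structure(list(summary = do.call(rbind, rows), diffs = diffs,
                 truths = truths, covariates = covs, config = config),
            class = "scale_simulation")
}

#' @export
print.scale_simulation <- function(x, ...) {
  cat(sprintf("scale-of-effect simulation: %d reps x %d scenarios, %d sites\n",
              x$config$n_reps, length(x$config$beta_true),
              x$config$n_sites))
  s <- x$summary
  s$mad <- signif(s$mad, 3)
  s$rmse <- signif(s$rmse, 3)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Univariate screening of several covariates
#'
#' Computes the `(K + 1)`-model posterior independently for each variable
#' under a shared model prior: the joint space over all variables is never
#' enumerated. Variables are ranked by the posterior probability of their
#' no-association model (ascending); those below `threshold` are flagged
#' as worth further investigation.
#'
#' @param y response vector.
#' @param covariate_sets named list of [site_covariates()], one per
#'   variable, sharing the same extents and sites.
#' @param prior a [model_prior()] applied to every variable.
#' @param sigma2 known error variance.
#' @param mode `"exact"` (closed form) or `"infR"` (sampling estimate).
#' @param rj_config an [rj_config()] used when `mode = "infR"`.
#' @param coef_prior a [coef_prior()]; default standard normal.
#' @param threshold flag variables whose null-model posterior falls below
#'   this (default 0.5, the conventional prior null mass).
#' @return object of class `"screening_result"`: `probs` (list of
#'   [posterior_model_probs()] per variable), `summary` (ranked data frame
#'   with null probability, top extent and flag).
#' @export
screen_variables <- function(y, covariate_sets, prior, sigma2 = 1,
                             mode = c("exact", "infR"),
                             rj_config = NULL,
                             coef_prior = NULL, threshold = 0.5) {
  rj_config <- rj_config %||% scalesel::rj_config()
  mode <- match.arg(mode)
  if (!is.list(covariate_sets) || !length(covariate_sets))
    stop("'covariate_sets' must be a non-empty list", call. = FALSE)
  if (is.null(names(covariate_sets)))
    names(covariate_sets) <- vapply(covariate_sets, `[[`, "", "variable")
  ext <- covariate_sets[[1L]]$extents
  ids <- covariate_sets[[1L]]$site_ids
  for (v in covariate_sets) {
    if (!isTRUE(all.equal(v$extents, ext)))
      stop("all variables must share the same extents", call. = FALSE)
    if (!identical(v$site_ids, ids))
      stop("site ids are misaligned across variables", call. = FALSE)
  }
  seeds <- substream_seeds(rj_config$seed, length(covariate_sets))
  probs <- lapply(seq_along(covariate_sets), function(i) {
    covs <- covariate_sets[[i]]
    if (mode == "exact")
      exact_posterior_model_probs(y, covs, prior, sigma2, coef_prior)
    else {
      rj <- rj_config
      rj$seed <- seeds[[i]]
      run_infr(y, covs, prior, sigma2, coef_prior, config = rj)
    }
  })
  names(probs) <- names(covariate_sets)
  summ <- do.call(rbind, lapply(names(probs), function(v) {
    p <- as.numeric(probs[[v]]$prob)
    top <- which.max(p[-1L])
    data.frame(variable = v, null_prob = p[1L],
               top_extent_m = ext[top], top_extent_prob = p[top + 1L],
               flagged = p[1L] < threshold)
  }))
  summ <- summ[order(summ$null_prob), ]
  rownames(summ) <- NULL
  structure(list(probs = probs, summary = summ, extents = ext,
                 threshold = threshold, mode = mode),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, digits = 3, ...) {
  cat(sprintf("univariate screening (%s) of %d variables at %d extents\n",
              x$mode, length(x$probs), length(x$extents)))
  s <- x$summary
  s$null_prob <- round(s$null_prob, digits)
  s$top_extent_prob <- round(s$top_extent_prob, digits)
  print(s, row.names = FALSE)
  invisible(x)
}
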