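# Containers for extent-indexed covariates and model-space objects.

#' Candidate spatial extents
#'
#' Validates an ordered set of circular buffer radii (in meters). The radii
#' index the candidate models: model `k` uses the covariate summarised
#' within radius `radii_m[k]`, and model 0 is the intercept-only
#' no-association model.
#'
#' @param radii_m numeric vector of buffer radii in meters; strictly
#'   increasing, all positive, length at least 1.
#' @return the validated numeric vector of radii.
#' @examples
#' extent_grid(seq(500, 5000, by = 500))
#' @export
extent_grid <- function(radii_m) {
  if (!is.numeric(radii_m) || length(radii_m) < 1L)
    stop("'radii_m' must be a non-empty numeric vector", call. = FALSE)
  radii_m <- as.numeric(radii_m)
  if (any(!is.finite(radii_m)) || any(radii_m <= 0))
    stop("all radii must be finite and positive", call. = FALSE)
  if (length(radii_m) > 1L && any(diff(radii_m) <= 0))
    stop("radii must be strictly increasing", call. = FALSE)
  radii_m
}

#' Site-by-extent covariate table
#'
#' One landscape variable (e.g. proportion developed land) summarised at
#' every site within each candidate circular extent. Values are proportions
#' in `[0, 1]`; column `k` corresponds to `extents[k]`.
#'
#' @param values numeric matrix, sites in rows, extents in columns; all
#'   entries in `[0, 1]`.
#' @param extents radii as accepted by [extent_grid()]; length must equal
#'   `ncol(values)`.
#' @param site_ids optional character vector of site identifiers.
#' @param variable label for the landscape variable (used in column names
#'   and file output).
#' @return an object of class `"site_covariates"` with fields `values`,
#'   `extents`, `site_ids`, `variable`.
#' @examples
#' m <- matrix(runif(6), nrow = 3)
#' site_covariates(m, extents = c(500, 1000), variable = "developed")
#' @export
site_covariates <- function(values, extents, site_ids = NULL,
                            variable = "x") {
  extents <- extent_grid(extents)
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("'values' must be numeric", call. = FALSE)
  if (ncol(values) != length(extents))
    stop(sprintf("'values' has %d columns but %d extents were given",
                 ncol(values), length(extents)), call. = FALSE)
  bad <- which(!is.finite(values) | values < 0 | values > 1)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "covariate values must be proportions in [0, 1]; offending value %s at row %d, column %d",
      format(values[bad[1L]]), ij[1L], ij[2L]), call. = FALSE)
  }
  if (is.null(site_ids))
    site_ids <- sprintf("site_%d", seq_len(nrow(values)))
  site_ids <- as.character(site_ids)
  if (length(site_ids) != nrow(values))
    stop("'site_ids' length must match the number of rows", call. = FALSE)
  dimnames(values) <- list(site_ids,
                           paste0(variable, "_", format(extents,
                                                        trim = TRUE,
                                                        scientific = FALSE)))
  structure(list(values = values, extents = extents, site_ids = site_ids,
                 variable = variable),
            class = "site_covariates")
}

#' @export
print.site_covariates <- function(x, ...) {
  cat(sprintf("site_covariates: '%s', %d sites x %d extents (%s-%s m)\n",
              x$variable, nrow(x$values), length(x$extents),
              format(min(x$extents)), format(max(x$extents))))
  invisible(x)
}

n_extents <- function(covariates) length(covariates$extents)

#' Discrete prior over the model space
#'
#' Wraps and validates a probability vector over the `K + 1` models:
#' element 1 is the no-association (null, intercept-only) model and
#' elements `2 ... K + 1` are the extent models in increasing-radius order.
#'
#' @param weights numeric vector of `K + 1` nonnegative probabilities
#'   summing to 1 (within `1e-12`).
#' @param extents optional radii labelling the extent models.
#' @return an object of class `"model_prior"`: the named weight vector with
#'   an `"extents_m"` attribute.
#' @seealso [point_mass_prior()], [stair_step_prior()], [bump_weight()]
#' @export
model_prior <- function(weights, extents = NULL) {
  if (!is.numeric(weights) || length(weights) < 1L)
    stop("'weights' must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("prior weights must be nonnegative and finite", call. = FALSE)
  s <- sum(weights)
  if (abs(s - 1) > 1e-12)
    stop(sprintf("prior weights must sum to 1 (got %.15g)", s),
         call. = FALSE)
  K <- length(weights) - 1L
  if (!is.null(extents)) {
    extents <- extent_grid(extents)
    if (length(extents) != K)
      stop("'extents' must have one radius per extent model", call. = FALSE)
  }
  nm <- c("null", if (!is.null(extents))
    format(extents, trim = TRUE, scientific = FALSE)
    else if (K > 0) paste0("extent_", seq_len(K)))
  structure(setNames(as.numeric(weights), nm), extents_m = extents,
            class = "model_prior")
}

#' @export
print.model_prior <- function(x, ...) {
  cat(sprintf("model_prior over %d models (null + %d extents)\n",
              length(x), length(x) - 1L))
  print(setNames(round(as.numeric(x), 4), names(x)))
  invisible(x)
}

#' Posterior model probabilities
#'
#' Container returned by every estimator in the package: the probability of
#' the null model and of each extent model, with a per-model Monte Carlo
#' error (zero for exact computation) and a method label.
#'
#' @param prob numeric vector of `K + 1` probabilities (null first) summing
#'   to 1 within `1e-10`.
#' @param mc_error nonnegative Monte Carlo standard errors, same length.
#' @param method one of `"exact"`, `"infR"`, `"SS"`, `"BLISS"`.
#' @param extents optional radii labelling the extent models.
#' @return an object of class `"posterior_model_probs"`.
#' @export
posterior_model_probs <- function(prob, mc_error = NULL,
                                  method = c("exact", "infR", "SS", "BLISS"),
                                  extents = NULL) {
  method <- match.arg(method)
  if (is.null(mc_error)) mc_error <- numeric(length(prob))
  if (length(mc_error) != length(prob))
    stop("'mc_error' must match 'prob' in length", call. = FALSE)
  if (any(!is.finite(prob)) || any(prob < -1e-10) || any(prob > 1 + 1e-10))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(prob) - 1) > 1e-10)
    stop(sprintf("probabilities must sum to 1 (got %.15g)", sum(prob)),
         call. = FALSE)
  if (any(mc_error < 0)) stop("'mc_error' must be nonnegative", call. = FALSE)
  prob <- pmin(pmax(as.numeric(prob), 0), 1)
  K <- length(prob) - 1L
  nm <- c("null", if (!is.null(extents))
    format(extent_grid(extents), trim = TRUE, scientific = FALSE)
    else if (K > 0) paste0("extent_", seq_len(K)))
  structure(list(model = nm, prob = setNames(prob, nm),
                 mc_error = setNames(as.numeric(mc_error), nm),
                 method = method, extents = extents),
            class = "posterior_model_probs")
}

#' @export
print.posterior_model_probs <- function(x, digits = 4, ...) {
  cat(sprintf("posterior model probabilities (%s)\n", x$method))
  df <- as.data.frame(x)
  df$prob <- round(df$prob, digits)
  df$mc_error <- signif(df$mc_error, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.posterior_model_probs <- function(x, ...) {
  data.frame(model = x$model, prob = as.numeric(x$prob),
             mc_error = as.numeric(x$mc_error), method = x$method,
             stringsAsFactors = FALSE)
}
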