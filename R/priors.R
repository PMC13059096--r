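# Programmatic construction of informed discrete priors over the model
# space: a point mass on the no-association model plus weights across the
# candidate extents.

#' Prior with a point mass on the no-association model
#'
#' Places `null_mass` on the intercept-only model and rescales the supplied
#' extent weights to sum to `1 - null_mass`. This is the programmatic
#' counterpart of interactive prior elicitation over extents.
#'
#' @param null_mass probability in `[0, 1]` that the covariate is not
#'   meaningful at any extent.
#' @param extent_weights `K` nonnegative relative weights over the extents;
#'   at least one must be positive unless `null_mass = 1`.
#' @param extents optional radii labelling the extent models.
#' @return a [model_prior()] of length `K + 1`.
#' @examples
#' point_mass_prior(0.4, rep(1, 6))
#' @export
point_mass_prior <- function(null_mass, extent_weights, extents = NULL) {
  stopifnot_scalar(null_mass, "null_mass")
  if (null_mass < 0 || null_mass > 1)
    stop("'null_mass' must lie in [0, 1]", call. = FALSE)
  extent_weights <- as.numeric(extent_weights)
  if (any(!is.finite(extent_weights)) || any(extent_weights < 0))
    stop("extent weights must be nonnegative", call. = FALSE)
  s <- sum(extent_weights)
  if (null_mass < 1 && s == 0)
    stop("at least one extent weight must be positive when null_mass < 1",
         call. = FALSE)
  w <- if (null_mass == 1) rep(0, length(extent_weights))
  else extent_weights / s * (1 - null_mass)
  model_prior(c(null_mass, w), extents = extents)
}

#' Stair-step prior over extents
#'
#' Splits `1 - null_mass` across `K` extents in symmetric ascending then
#' descending integer proportions `(1, 2, ..., ceiling(K/2),
#' floor(K/2), ..., 2, 1)`, encoding the belief that mid-range extents are
#' a priori most plausible (a researcher choosing the candidate range will
#' usually pad both ends). With `K = 10` and `null_mass = 0.5` the extent
#' weights are `(1, 2, 3, 4, 5, 5, 4, 3, 2, 1) / 60`.
#'
#' @param n_extents number of candidate extents, at least 2.
#' @param null_mass prior probability of the no-association model.
#' @param extents optional radii labelling the extent models.
#' @return a [model_prior()] of length `n_extents + 1`.
#' @examples
#' stair_step_prior(10, null_mass = 0.5)
#' @export
stair_step_prior <- function(n_extents, null_mass = 0.5, extents = NULL) {
  if (!is.numeric(n_extents) || length(n_extents) != 1L ||
      n_extents != round(n_extents) || n_extents < 2)
    stop("'n_extents' must be an integer >= 2", call. = FALSE)
  K <- as.integer(n_extents)
  up <- seq_len(ceiling(K / 2))
  w <- c(up, rev(seq_len(floor(K / 2))))
  point_mass_prior(null_mass, w, extents = extents)
}

#' Reweight one model in a prior
#'
#' Multiplies the weight of a single model by `factor` and renormalises the
#' whole vector, mimicking the click-to-adjust step of interactive
#' elicitation.
#'
#' @param prior a [model_prior()].
#' @param model_index model to adjust: 0 for the null model, `k >= 1` for
#'   the `k`-th extent.
#' @param factor positive multiplier.
#' @return the renormalised [model_prior()].
#' @examples
#' bump_weight(point_mass_prior(0.5, c(1, 1)), model_index = 1, factor = 3)
#' @export
bump_weight <- function(prior, model_index, factor) {
  if (!inherits(prior, "model_prior"))
    stop("'prior' must be a model_prior", call. = FALSE)
  stopifnot_scalar(factor, "factor", positive = TRUE)
  K <- length(prior) - 1L
  if (!is.numeric(model_index) || length(model_index) != 1L ||
      model_index != round(model_index) || model_index < 0 ||
      model_index > K)
    stop(sprintf("'model_index' must be an integer in 0..%d", K),
         call. = FALSE)
  w <- as.numeric(prior)
  w[model_index + 1L] <- w[model_index + 1L] * factor
  model_prior(w / sum(w), extents = attr(prior, "extents_m"))
}
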