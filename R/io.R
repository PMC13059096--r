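# Delimited-text and JSON dialects: covariates as CSV with a site_id
# column and "<variable>_<radius_m>" columns, responses as (site_id, y)
# CSV, priors and posterior model probabilities as JSON.

#' Write site-by-extent covariates to CSV
#'
#' @param covariates a [site_covariates()] or a list of them sharing
#'   sites (columns are concatenated).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  if (inherits(covariates, "site_covariates"))
    covariates <- list(covariates)
  ids <- covariates[[1L]]$site_ids
  mats <- lapply(covariates, function(v) {
    if (!identical(v$site_ids, ids))
      stop("all variables must share the same sites", call. = FALSE)
    v$values
  })
  df <- data.frame(site_id = ids, do.call(cbind, mats),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read site-by-extent covariates from CSV
#'
#' Expects a `site_id` column plus columns named `<variable>_<radius_m>`;
#' columns are grouped by variable prefix and each group must form a valid
#' increasing extent grid with values in `[0, 1]`.
#'
#' @param path CSV file.
#' @return named list of [site_covariates()], one per variable (a single
#'   variable still comes back as a length-1 list).
#' @export
read_covariates <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"site_id" %in% names(df))
    stop(sprintf("'%s' has no site_id column", path), call. = FALSE)
  ids <- as.character(df$site_id)
  cols <- setdiff(names(df), "site_id")
  if (!length(cols))
    stop(sprintf("'%s' has no covariate columns", path), call. = FALSE)
  m <- regmatches(cols, regexec("^(.*)_([0-9]+(?:\\.[0-9]+)?)$", cols))
  bad <- cols[vapply(m, length, 0L) != 3L]
  if (length(bad))
    stop(sprintf("column '%s' is not named <variable>_<radius_m>", bad[1L]),
         call. = FALSE)
  vars <- vapply(m, `[[`, "", 2L)
  radii <- as.numeric(vapply(m, `[[`, "", 3L))
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v))
      stop(sprintf("column '%s' contains non-numeric values", col),
           call. = FALSE)
    off <- which(!is.finite(v) | v < 0 | v > 1)
    if (length(off))
      stop(sprintf(
        "value %s in row %d, column '%s' is not a proportion in [0, 1]",
        format(v[off[1L]]), off[1L], col), call. = FALSE)
  }
  out <- lapply(split(seq_along(cols), vars), function(ix) {
    o <- order(radii[ix])
    site_covariates(as.matrix(df[cols[ix][o]]), extents = radii[ix][o],
                    site_ids = ids, variable = vars[ix[1L]])
  })
  out[unique(vars)]
}

#' Write / read a response vector as (site_id, y) CSV
#'
#' @param y numeric response vector.
#' @param site_ids site identifiers aligned with `y`.
#' @param path CSV file.
#' @return `write_response()` returns `path` invisibly; `read_response()`
#'   returns a named numeric vector (names = site ids).
#' @export
write_response <- function(y, site_ids, path) {
  if (length(y) != length(site_ids))
    stop("'y' and 'site_ids' must have the same length", call. = FALSE)
  write.csv(data.frame(site_id = as.character(site_ids), y = as.numeric(y)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response
#' @export
read_response <- function(path) {
  df <- read.csv(path)
  if (!all(c("site_id", "y") %in% names(df)))
    stop(sprintf("'%s' must have site_id and y columns", path),
         call. = FALSE)
  if (!is.numeric(df$y))
    stop("response column 'y' must be numeric", call. = FALSE)
  setNames(df$y, as.character(df$site_id))
}

#' Serialise a model prior to / from JSON
#'
#' Schema: `{"null": w0, "extents_m": [...], "weights": [...]}` with
#' `weights` aligned to `extents_m`.
#'
#' @param prior a [model_prior()].
#' @param path JSON file.
#' @return `write_prior_json()` returns `path` invisibly;
#'   `read_prior_json()` returns a [model_prior()].
#' @export
write_prior_json <- function(prior, path) {
  jsonlite::write_json(prior_to_list(prior), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

prior_to_list <- function(prior) {
  w <- as.numeric(prior)
  list(null = w[1L], extents_m = attr(prior, "extents_m"),
       weights = w[-1L])
}

#' @rdname write_prior_json
#' @export
read_prior_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_prior(c(x$null, x$weights), extents = x$extents_m)
}

#' Serialise posterior model probabilities to JSON
#'
#' Records of the form `{"model": "null" | radius_m, "prob": ...,
#' "mc_error": ...}` plus the method label.
#'
#' @param pmp a [posterior_model_probs()].
#' @param path JSON file.
#' @return `path`, invisibly.
#' @export
write_pmp_json <- function(pmp, path) {
  recs <- lapply(seq_along(pmp$prob), function(i) {
    mod <- if (i == 1L) "null"
    else if (!is.null(pmp$extents)) pmp$extents[i - 1L]
    else pmp$model[i]
    list(model = mod, prob = as.numeric(pmp$prob[i]),
         mc_error = as.numeric(pmp$mc_error[i]))
  })
  jsonlite::write_json(list(method = pmp$method, models = recs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
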