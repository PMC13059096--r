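# Base-graphics displays: lollipop charts of priors and posteriors, a
# screening panel, and boxplots of estimation error by model.

#' @export
plot.model_prior <- function(x, main = "prior model probabilities", ...) {
  w <- as.numeric(x)
  at <- seq_along(w)
  plot(at, w, type = "h", lwd = 2, xaxt = "n", xlab = "model",
       ylab = "prior probability", ylim = c(0, max(w) * 1.15),
       main = main, ...)
  points(at, w, pch = 19)
  axis(1, at = at, labels = names(x), las = 2, cex.axis = 0.8)
  invisible(x)
}

#' @export
plot.posterior_model_probs <- function(x, main = NULL, ...) {
  p <- as.numeric(x$prob)
  at <- seq_along(p)
  plot(at, p, type = "h", lwd = 2, xaxt = "n", xlab = "model",
       ylab = "posterior probability", ylim = c(0, max(p) * 1.15),
       main = main %||% sprintf("posterior model probabilities (%s)",
                                x$method), ...)
  points(at, p, pch = 19)
  err <- as.numeric(x$mc_error)
  if (any(err > 0))
    segments(at, pmax(p - 2 * err, 0), at, pmin(p + 2 * err, 1),
             col = "grey40")
  axis(1, at = at, labels = x$model, las = 2, cex.axis = 0.8)
  invisible(x)
}

#' @export
plot.screening_result <- function(x, ...) {
  nv <- length(x$probs)
  nc <- ceiling(sqrt(nv))
  nr <- ceiling(nv / nc)
  op <- par(mfrow = c(nr, nc), mar = c(4.5, 4, 2, 0.5))
  on.exit(par(op), add = TRUE)
  for (v in names(x$probs)) plot(x$probs[[v]], main = v)
  invisible(x)
}

#' @export
plot.scale_simulation <- function(x, method = NULL, ...) {
  method <- method %||% names(x$diffs)[1L]
  d <- x$diffs[[method]]
  scen <- names(d)
  op <- par(mfrow = c(length(scen), 1), mar = c(4.5, 4, 2, 0.5))
  on.exit(par(op), add = TRUE)
  labels <- c("null", format(x$config$extents, trim = TRUE))
  for (s in scen) {
    graphics::boxplot(as.data.frame(d[[s]]), names = labels, las = 2,
                      outline = FALSE, cex.axis = 0.7,
                      ylab = "estimate - truth",
                      main = sprintf("%s, %s association", method, s))
    abline(h = 0, col = "grey60", lty = 2)
    points(seq_along(labels), colMeans(d[[s]]), col = "red", pch = 19)
  }
  invisible(x)
}
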