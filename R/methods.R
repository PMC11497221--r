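#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("Linear rate fit over %d points: slope = %.6g +/- %.2g, r2 = %.4f\n",
              length(x$window), x$slope, x$stderr_slope, x$r_squared))
  invisible(x)
}

#' @export
print.pfo_fit <- function(x, ...) {
  cat(sprintf("Pseudo-first-order fit over %d points: k_obs = %.6g +/- %.2g min^-1 (r2 = %.4f)\n",
              length(x$window), x$kobs, x$stderr_kobs, x$r_squared))
  invisible(x)
}

#' @export
print.k2_fit <- function(x, ...) {
  cat(sprintf("k_obs vs [excess] regression (%d levels): k2 = %.6g +/- %.2g mM^-1 min^-1, intercept = %.3g min^-1\n",
              nrow(x$data), x$slope, x$stderr_slope, x$intercept))
  invisible(x)
}

#' @export
summary.rate_fit <- function(object, ...) {
  print(object)
  summary(object$fit, ...)
}

#' @export
coef.rate_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.rate_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  x <- if (is.list(newdata)) newdata[[1L]] else newdata
  object$intercept + object$slope * x
}

#' @export
residuals.rate_fit <- function(object, ...) {
  stats::residuals(object$fit)
}

#' @export
plot.rate_fit <- function(x, ..., xlab = NULL, ylab = NULL) {
  d <- x$data
  if (is.null(xlab)) xlab <- names(d)[1L]
  if (is.null(ylab)) ylab <- names(d)[2L]
  graphics::plot(d[[1L]], d[[2L]], pch = 16, xlab = xlab, ylab = ylab, ...)
  graphics::abline(x$intercept, x$slope, col = "steelblue")
  invisible(x)
}

#' @export
print.order_fit <- function(x, ...) {
  cat(sprintf("Log-log order fit (%d points): order = %.4f +/- %.3g, r2 = %.4f\n",
              nrow(x$points), x$order, x$stderr, x$r_squared))
  invisible(x)
}

#' @export
coef.order_fit <- function(object, ...) {
  c(intercept = object$intercept, order = object$order)
}

#' @export
plot.order_fit <- function(x, ..., xlab = "log10 [conc] (mM)",
                           ylab = "log10 rate") {
  graphics::plot(x$points$log10_conc, x$points$log10_rate, pch = 16,
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(x$intercept, x$order, col = "steelblue")
  invisible(x)
}

#' @export
print.hammett_fit <- function(x, ...) {
  cat(sprintf("Hammett fit (%d substituents, ref %s): rho = %.3f +/- %.3f, r2 = %.4f\n",
              nrow(x$points), x$reference, x$rho, x$stderr_rho,
              x$r_squared))
  invisible(x)
}

#' @export
coef.hammett_fit <- function(object, ...) {
  c(intercept = object$intercept, rho = object$rho)
}

#' @export
summary.hammett_fit <- function(object, ...) {
  print(object)
  print(object$points)
  invisible(object)
}

#' @export
plot.hammett_fit <- function(x, ..., xlab = expression(sigma),
                             ylab = expression(log[10](k[X] / k[H]))) {
  graphics::plot(x$points$sigma, x$points$log_ratio, pch = 16,
                 xlab = xlab, ylab = ylab, ...)
  graphics::text(x$points$sigma, x$points$log_ratio,
                 x$points$substituent, pos = 3, cex = 0.7)
  graphics::abline(x$intercept, x$rho, col = "steelblue")
  invisible(x)
}

#' @export
print.vtna_fit <- function(x, ...) {
  cat(sprintf("VTNA order scan in '%s' (observing '%s'): best alpha = %g\n",
              x$varied, x$observed, x$best_alpha))
  cat(sprintf("  grid %g..%g (%d values), min overlay RMSD = %.3g\n",
              min(x$grid), max(x$grid), length(x$grid), min(x$scores)))
  invisible(x)
}

#' @export
plot.vtna_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$grid, x$scores, type = "l", xlab = expression(alpha),
                 ylab = "overlay RMSD", ...)
  graphics::abline(v = x$best_alpha, lty = 2, col = "grey40")
  rng_x <- range(unlist(lapply(x$profiles, `[[`, "t_norm")))
  rng_y <- range(unlist(lapply(x$profiles, `[[`, "value")))
  graphics::plot(NA, xlim = rng_x, ylim = rng_y,
                 xlab = sprintf("normalized time (alpha = %g)", x$best_alpha),
                 ylab = x$observed)
  for (i in seq_along(x$profiles))
    graphics::lines(x$profiles[[i]]$t_norm, x$profiles[[i]]$value,
                    col = i, lty = 1)
  invisible(x)
}
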