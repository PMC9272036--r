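#' @export
print.polymr <- function(x, digits = 4, ...) {
  cat("Polynomial MR fit (control-function, k =", x$k, ", l =", x$l, ")\n")
  cat(sprintf("  n = %d samples, %d of %d instruments used\n",
              x$n, x$iv$n_used, x$iv$n_initial))
  cat("  retained exposure orders:",
      paste(x$k_retained, collapse = ", "), "\n")
  cat("  exposure coefficients (per SD of exposure/outcome):\n")
  print(round(x$alpha_hat, digits))
  cat(sprintf("  non-linearity p = %.3g, causally explained variance = %.4g\n",
              x$nonlinearity_p, x$causal_r2))
  invisible(x)
}

#' Summarize a polynomial MR fit
#'
#' @param object A [polymr()] fit.
#' @param ... Unused.
#' @return An object of class `summary.polymr` containing the coefficient
#'   table (estimate, standard error, t value, two-sided p value), the
#'   non-linearity p value, the causally explained variance, log
#'   likelihoods, instrument counts before and after the
#'   reverse-causation filter, and the backward-selection trace.
#' @export
summary.polymr <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `t value` = object$coefficients / object$se,
               `Pr(>|t|)` = object$pvalues)
  structure(list(call = object$call, coefficients = tab,
                 k = object$k, l = object$l,
                 k_retained = object$k_retained,
                 l_retained = object$l_retained,
                 nonlinearity_p = object$nonlinearity_p,
                 causal_r2 = object$causal_r2,
                 loglik_full = object$loglik_full,
                 loglik_linear = object$loglik_linear,
                 selection_trace = object$selection_trace,
                 iv = object$iv, n = object$n,
                 n_dropped = object$n_dropped),
            class = "summary.polymr")
}

#' @export
print.summary.polymr <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat(sprintf("n = %d (%d incomplete rows dropped)\n", x$n, x$n_dropped))
  cat(sprintf("Instruments: %d supplied, %d used%s\n", x$iv$n_initial,
              x$iv$n_used,
              if (x$iv$reverse_filter) " (after reverse-causation filter)"
              else ""))
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (length(x$selection_trace) > 0L) {
    elim <- vapply(x$selection_trace, function(t) t$order, integer(1))
    cat("\nEliminated exposure orders (in order):",
        paste(elim, collapse = ", "), "\n")
  }
  cat(sprintf("\nNon-linearity LRT p value: %.4g\n", x$nonlinearity_p))
  cat(sprintf("Causally explained variance: %.4g\n", x$causal_r2))
  invisible(x)
}

#' @export
coef.polymr <- function(object, ...) object$coefficients

#' @export
vcov.polymr <- function(object, robust = FALSE, ...) {
  if (robust) {
    if (is.null(object$vcov_robust))
      stop("refit with `robust = TRUE` for the HC0 covariance",
           call. = FALSE)
    return(object$vcov_robust)
  }
  object$vcov
}

#' @export
residuals.polymr <- function(object, ...) object$residuals

#' @export
fitted.polymr <- function(object, ...) object$fitted.values

#' @export
logLik.polymr <- function(object, ...) {
  structure(object$loglik_full,
            df = length(object$coefficients) + 1L,
            nobs = object$n, class = "logLik")
}

#' Causal curve with 95% confidence hull
#'
#' Evaluates the fitted causal polynomial on a grid of exposure values,
#' anchored to zero at the mean exposure (curves show the expected change
#' in outcome relative to the outcome level at the mean population
#' exposure). The confidence hull is obtained by drawing coefficient
#' vectors from their estimated multivariate normal distribution,
#' anchoring each drawn curve the same way, and taking pointwise
#' percentiles.
#'
#' @param object A [polymr()] fit.
#' @param grid Exposure values at which to evaluate the curve; defaults to
#'   percentiles 1-99 of the in-sample exposure.
#' @param n_draws Number of coefficient draws for the hull (>= 100;
#'   default 10,000).
#' @param level Hull coverage level (default 0.95).
#' @param seed Optional seed making the hull reproducible.
#' @param scale `"sd"` (default) interprets `grid` and reports the curve in
#'   standard-deviation units of exposure and outcome; `"original"` uses
#'   the input units of both traits.
#' @param ... Unused.
#' @return A `polymr_curve` data frame with columns `grid`, `estimate`,
#'   `lower`, `upper`.
#' @export
predict.polymr <- function(object, grid = NULL, n_draws = 10000,
                           level = 0.95, seed = NULL,
                           scale = c("sd", "original"), ...) {
  scale <- match.arg(scale)
  if (n_draws < 100) stop("`n_draws` must be >= 100", call. = FALSE)
  if (is.null(grid)) {
    grid_sd <- unname(stats::quantile(object$exposure_std, (1:99) / 100))
    grid_out <- if (scale == "sd") grid_sd else
      grid_sd * object$x_scale + object$x_center
  } else {
    grid_out <- grid
    grid_sd <- if (scale == "sd") grid else
      (grid - object$x_center) / object$x_scale
  }
  orders <- object$k_retained
  idx <- paste0("x^", orders)
  a <- object$coefficients[idx]
  # Anchor: the mean exposure is 0 on the standardized scale, where every
  # power vanishes, so the anchored curve is just the polynomial without
  # intercept.
  P <- outer_powers(grid_sd, orders)
  est <- as.vector(P %*% a)
  S <- object$vcov[idx, idx, drop = FALSE]
  draws <- with_seed(seed, mvn_draws(n_draws, a, S))
  curves <- P %*% t(draws)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  bounds <- apply(curves, 1L, stats::quantile, probs = qs)
  yfac <- if (scale == "sd") 1 else object$y_scale
  out <- data.frame(grid = grid_out, estimate = est * yfac,
                    lower = bounds[1L, ] * yfac,
                    upper = bounds[2L, ] * yfac)
  structure(out, n_draws = n_draws, level = level, scale = scale,
            class = c("polymr_curve", "data.frame"))
}

outer_powers <- function(g, orders) {
  P <- vapply(orders, function(j) g^j, numeric(length(g)))
  matrix(P, nrow = length(g), ncol = length(orders))
}

# Multivariate normal draws; if the covariance is numerically indefinite,
# clip its eigenvalues at zero and retry.
mvn_draws <- function(n, mu, Sigma) {
  tryCatch(MASS::mvrnorm(n, mu, Sigma),
    error = function(e) {
      es <- eigen(Sigma, symmetric = TRUE)
      if (min(es$values) < -1e-6 * max(abs(es$values)))
        warning("coefficient covariance is not positive semi-definite; ",
                "eigenvalues clipped at 0", call. = FALSE)
      S2 <- es$vectors %*% diag(pmax(es$values, 0),
                                length(es$values)) %*% t(es$vectors)
      MASS::mvrnorm(n, mu, S2, tol = 1)
    })
}

#' @export
print.polymr_curve <- function(x, ...) {
  cat(sprintf("Causal curve on %d grid points (%g%% hull, %d draws, %s scale)\n",
              nrow(x), 100 * attr(x, "level"), attr(x, "n_draws"),
              attr(x, "scale")))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Plot the estimated causal curve
#'
#' @param x A [polymr()] fit or a `polymr_curve`.
#' @param curve Optionally a precomputed curve (otherwise
#'   [predict.polymr()] is called).
#' @param truth Optional function of the grid to overlay (anchored at the
#'   mean exposure internally).
#' @param ... Further arguments to [predict.polymr()] (for `polymr`
#'   objects) or [graphics::plot()].
#' @return The curve, invisibly.
#' @export
plot.polymr <- function(x, curve = NULL, truth = NULL, ...) {
  if (is.null(curve)) curve <- stats::predict(x, ...)
  plot(curve, truth = truth)
}

#' @rdname plot.polymr
#' @export
plot.polymr_curve <- function(x, truth = NULL, ...) {
  graphics::plot(x$grid, x$estimate, type = "n",
                 ylim = range(x$lower, x$upper),
                 xlab = "Exposure", ylab = "Outcome (relative to mean exposure)",
                 ...)
  graphics::polygon(c(x$grid, rev(x$grid)), c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor("purple", 0.2),
                    border = NA)
  graphics::lines(x$grid, x$estimate, col = "purple", lwd = 2)
  if (!is.null(truth)) {
    tv <- truth(x$grid)
    anchor <- truth(x$grid[which.min(abs(x$grid))])
    graphics::lines(x$grid, tv - anchor, col = "darkgreen", lty = 2)
  }
  graphics::abline(h = 0, v = 0, col = "grey80")
  invisible(x)
}

#' Simulate outcomes from a fitted polynomial MR model
#'
#' Draws new outcome vectors from the fitted second-stage model (design
#' held fixed, Gaussian residual noise at the estimated variance), on the
#' scale of the original outcome.
#'
#' @param object A [polymr()] fit.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns.
#' @export
simulate.polymr <- function(object, nsim = 1, seed = NULL, ...) {
  n <- object$n
  with_seed(seed, {
    out <- replicate(nsim,
      (object$fitted.values + stats::rnorm(n, sd = sqrt(object$sigma2))) *
        object$y_scale + object$y_center)
    out <- as.data.frame(out)
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}
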