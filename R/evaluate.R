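#' Run replicate simulations and aggregate estimator performance
#'
#' For each replicate: simulate a dataset under `settings`, select
#' instruments by marginal genome-wide significance, fit the estimator, and
#' evaluate the anchored causal curve on a fixed grid of true-exposure
#' percentiles. Aggregates bias, RMSE, predicted and empirical confidence
#' interval widths, truth coverage, polynomial-order detection counts, and
#' mean coefficients.
#'
#' Per-replicate seeds are derived deterministically from `seed`, so results
#' are reproducible and independent of execution order. Replicates in which
#' no instrument reaches the significance threshold are skipped with a
#' warning and counted.
#'
#' @param settings A [polymr_settings()] object (its `seed` is overridden
#'   per replicate).
#' @param n_reps Number of replicates (>= 2).
#' @param method `"polymr"` (full polynomial control function) or
#'   `"polymr_l1"` (first-order control function).
#' @param seed Master seed for the replicate stream.
#' @param k,l Polynomial orders passed to the estimator.
#' @param select Backward selection flag passed to the estimator.
#' @param n_draws Coefficient draws per replicate for the confidence hull.
#' @param grid Exposure grid (standardized scale); defaults to the 1-99
#'   percentiles of the standard normal, the true exposure distribution.
#' @param progress Print a dot every 10 replicates?
#' @return An object of class `polymr_replicates` with per-percentile
#'   `mean_bias`, `rmse`, `predicted_ci_width`, `empirical_ci_width`,
#'   `coverage`, the `detection` counts of the highest retained exposure
#'   order, `mean_alpha` and the per-replicate `alpha_estimates`
#'   (eliminated coefficients counted as zero),
#'   `nonlinearity_rejection_rate`, the per-replicate matrices, and the
#'   scenario echo.
#' @examples
#' st <- polymr_settings(n_samples = 2000, n_causal_snps = 10,
#'                       gwas_p_threshold = 1e-4, seed = 1)
#' run_replicates(st, n_reps = 3, n_draws = 200)
#' @export
run_replicates <- function(settings, n_reps, method = c("polymr",
                                                        "polymr_l1"),
                           seed = 1, k = 10, l = if (method == "polymr_l1")
                             1L else k, select = TRUE, n_draws = 1000,
                           grid = stats::qnorm((1:99) / 100),
                           progress = FALSE) {
  method <- match.arg(method)
  if (!inherits(settings, "polymr_settings"))
    stop("`settings` must be built with polymr_settings()", call. = FALSE)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 2L)
    stop("`n_reps` must be >= 2", call. = FALSE)
  seeds <- derive_seeds(seed, 2L * n_reps)
  rep_seeds <- seeds[seq_len(n_reps)]
  hull_seeds <- seeds[n_reps + seq_len(n_reps)]

  P <- length(grid)
  est <- matrix(NA_real_, n_reps, P)
  lo <- matrix(NA_real_, n_reps, P)
  up <- matrix(NA_real_, n_reps, P)
  alpha <- matrix(0, n_reps, k + 1L)
  highest <- integer(n_reps)
  nonlin_p <- rep(NA_real_, n_reps)
  causal_r2 <- rep(NA_real_, n_reps)
  n_ivs <- integer(n_reps)
  ok <- logical(n_reps)

  for (i in seq_len(n_reps)) {
    st <- settings
    st$seed <- rep_seeds[i]
    d <- simulate_dataset(st)
    ivs <- select_instruments(d)
    if (length(ivs) == 0L) {
      warning("replicate ", i, ": no instrument reached p < ",
              st$gwas_p_threshold, "; skipped", call. = FALSE)
      next
    }
    fit <- tryCatch(
      if (method == "polymr_l1")
        polymr_l1(d$exposure, d$outcome, d$genotypes[, ivs, drop = FALSE],
                  k = k, select = select)
      else
        polymr(d$exposure, d$outcome, d$genotypes[, ivs, drop = FALSE],
               k = k, l = l, select = select),
      error = function(e) {
        warning("replicate ", i, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    cv <- stats::predict(fit, grid = grid, n_draws = n_draws,
                         seed = hull_seeds[i], scale = "sd")
    est[i, ] <- cv$estimate
    lo[i, ] <- cv$lower
    up[i, ] <- cv$upper
    alpha[i, fit$k_retained + 1L] <- fit$alpha_hat[as.character(fit$k_retained)]
    alpha[i, 1L] <- fit$alpha_hat["0"]
    highest[i] <- max(fit$k_retained)
    nonlin_p[i] <- fit$nonlinearity_p
    causal_r2[i] <- fit$causal_r2
    n_ivs[i] <- fit$iv$n_used
    ok[i] <- TRUE
    if (progress && i %% 10L == 0L) cat(".")
  }
  if (progress) cat("\n")
  if (sum(ok) < 2L)
    stop("fewer than two replicates completed", call. = FALSE)

  truth <- anchored_truth(settings$causal_function, grid)
  est_ok <- est[ok, , drop = FALSE]
  lo_ok <- lo[ok, , drop = FALSE]
  up_ok <- up[ok, , drop = FALSE]
  cal <- ci_calibration(est_ok, lo_ok, up_ok, truth,
                        warn_few = FALSE)
  rm <- rmse_curve(est_ok, truth, anchor = FALSE)
  det <- table(factor(highest[ok], levels = seq_len(k)))

  structure(list(
    scenario = settings, method = method, n_reps = n_reps,
    n_completed = sum(ok), n_skipped = sum(!ok),
    grid = grid, truth = truth,
    mean_bias = colMeans(est_ok) - truth,
    rmse = rm$rmse,
    rmse_mean = rm$mean, rmse_ci = rm$ci,
    predicted_ci_width = cal$predicted_width,
    empirical_ci_width = cal$empirical_width,
    coverage = cal$coverage,
    detection = det,
    mean_alpha = stats::setNames(colMeans(alpha[ok, , drop = FALSE]),
                                 0:k),
    alpha_estimates = structure(alpha[ok, , drop = FALSE],
                                dimnames = list(NULL, 0:k)),
    nonlinearity_rejection_rate = mean(nonlin_p[ok] < 0.05),
    mean_causal_r2 = mean(causal_r2[ok]),
    mean_n_ivs = mean(n_ivs[ok]),
    estimates = est_ok, lower = lo_ok, upper = up_ok,
    highest_order = highest[ok], nonlinearity_p = nonlin_p[ok]),
    class = "polymr_replicates")
}

anchored_truth <- function(causal_function, grid) {
  evaluate_causal_function(causal_function, grid) -
    evaluate_causal_function(causal_function, 0)
}

#' @export
print.polymr_replicates <- function(x, ...) {
  cat(sprintf("Replicate summary: %d/%d replicates completed (%s)\n",
              x$n_completed, x$n_reps, x$method))
  cat(sprintf("  mean |bias| over grid: %.4g, mean RMSE: %.4g (95%% CI %.4g-%.4g)\n",
              mean(abs(x$mean_bias)), x$rmse_mean, x$rmse_ci[1], x$rmse_ci[2]))
  cat(sprintf("  mean truth coverage of hulls: %.3f\n", mean(x$coverage)))
  cat("  highest retained exposure order:\n")
  print(x$detection)
  cat(sprintf("  non-linearity rejected at 5%% in %.1f%% of replicates\n",
              100 * x$nonlinearity_rejection_rate))
  cat("  mean exposure coefficients (order 0..):",
      paste(signif(x$mean_alpha[1:min(5, length(x$mean_alpha))], 3),
            collapse = ", "), "...\n")
  invisible(x)
}

#' @export
plot.polymr_replicates <- function(x, ...) {
  graphics::plot(x$grid, x$truth, type = "l", col = "darkgreen", lwd = 2,
                 xlab = "Exposure (SD)", ylab = "Outcome (anchored)",
                 ylim = range(x$truth, colMeans(x$estimates),
                              x$truth + x$mean_bias), ...)
  graphics::lines(x$grid, colMeans(x$estimates), col = "purple", lwd = 2,
                  lty = 2)
  graphics::legend("topleft", c("truth", "mean estimate"),
                   col = c("darkgreen", "purple"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Per-percentile bias of replicate causal-curve estimates
#'
#' Each curve (and the truth) is re-anchored by subtracting its value at
#' the grid point closest to `anchor`, making the bias level-free, and the
#' mean deviation from truth is returned per grid point.
#'
#' @param estimates Replicates x grid matrix of curve estimates.
#' @param truth Truth vector on the same grid (a `causal_fun` is also
#'   accepted, in which case `grid` must be supplied).
#' @param grid Optional grid (needed when `truth` is a `causal_fun`).
#' @param anchor Anchor point on the grid scale (default 0, the mean
#'   exposure).
#' @return Numeric vector of per-grid-point mean bias.
#' @export
bias_curve <- function(estimates, truth, grid = NULL, anchor = 0) {
  z <- align_curves(estimates, truth, grid, anchor)
  colMeans(z$est) - z$truth
}

#' Per-percentile and scenario-mean RMSE of replicate estimates
#'
#' @inheritParams bias_curve
#' @param anchor Anchor point, or `FALSE` to skip re-anchoring.
#' @return A list with `rmse` (per grid point), `mean` (scenario mean of
#'   per-replicate RMSEs) and `ci` (95% normal-approximation confidence
#'   interval of that mean).
#' @export
rmse_curve <- function(estimates, truth, grid = NULL, anchor = 0) {
  z <- align_curves(estimates, truth, grid, anchor)
  err <- sweep(z$est, 2L, z$truth)
  per_rep <- sqrt(rowMeans(err^2))
  m <- mean(per_rep)
  half <- stats::qnorm(0.975) * stats::sd(per_rep) / sqrt(length(per_rep))
  list(rmse = sqrt(colMeans(err^2)), mean = m, ci = c(m - half, m + half))
}

#' Confidence-interval calibration of replicate hulls
#'
#' Compares the theoretically predicted hull width (mean of upper minus
#' lower over replicates) with the empirical width (2.5-97.5 inter-
#' percentile range of the point estimates across replicates), and reports
#' the fraction of replicates whose hull contains the anchored truth, per
#' grid point.
#'
#' @param estimates,lower,upper Replicates x grid matrices.
#' @param truth Truth vector on the same grid.
#' @param warn_few Warn when fewer than 20 replicates are supplied?
#' @return A list with `predicted_width`, `empirical_width`, `coverage`.
#' @export
ci_calibration <- function(estimates, lower, upper, truth,
                           warn_few = TRUE) {
  if (!all(dim(estimates) == dim(lower)) ||
      !all(dim(estimates) == dim(upper)))
    stop("matrix dimensions differ", call. = FALSE)
  if (ncol(estimates) != length(truth))
    stop("grid mismatch between estimates and truth", call. = FALSE)
  if (warn_few && nrow(estimates) < 20L)
    warning("fewer than 20 replicates: calibration estimates are very ",
            "uncertain", call. = FALSE)
  tr <- rep(truth, each = nrow(estimates))
  list(
    predicted_width = colMeans(upper - lower),
    empirical_width = apply(estimates, 2L, function(v)
      diff(stats::quantile(v, c(0.025, 0.975)))),
    coverage = colMeans(lower <= tr & tr <= upper))
}

align_curves <- function(estimates, truth, grid, anchor) {
  estimates <- as.matrix(estimates)
  if (inherits(truth, "causal_fun")) {
    if (is.null(grid))
      stop("`grid` is required when `truth` is a causal_fun", call. = FALSE)
    truth <- evaluate_causal_function(truth, grid)
  }
  if (ncol(estimates) != length(truth))
    stop("grid mismatch: estimates have ", ncol(estimates),
         " columns but truth has length ", length(truth), call. = FALSE)
  if (!identical(anchor, FALSE)) {
    if (is.null(grid)) grid <- seq_along(truth)
    ai <- which.min(abs(grid - anchor))
    estimates <- estimates - estimates[, ai]
    truth <- truth - truth[ai]
  }
  list(est = estimates, truth = truth)
}
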