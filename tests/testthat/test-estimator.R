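test_that("standardize centers, scales, inverts and rejects constants", {
  z <- standardize(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_equal(attr(z, "center"), 2)
  expect_equal(attr(z, "scale"), 1)
  v <- rnorm(50, 5, 3)
  z2 <- standardize(v)
  expect_equal(as.numeric(standardize(as.numeric(z2))), as.numeric(z2),
               tolerance = 1e-12)
  expect_equal(as.numeric(z2) * attr(z2, "scale") + attr(z2, "center"), v)
  expect_error(standardize(rep(4, 10)), "constant")
})

test_that("first stage matches the normal-equation oracle", {
  fx <- tiny_fixture()
  oracle <- solve(t(fx$G) %*% fx$G) %*% t(fx$G) %*% fx$x
  fs <- fit_first_stage(fx$G, fx$x)
  expect_equal(unname(fs$beta_hat), as.vector(oracle), tolerance = 1e-10)
  expect_equal(fs$fitted_exposure + fs$residual_exposure, fx$x)
  # residual orthogonal to every instrument column and to the fit
  expect_lt(max(abs(crossprod(fx$G, fs$residual_exposure))), 1e-10)
  expect_lt(abs(sum(fs$fitted_exposure * fs$residual_exposure)), 1e-10)
})

test_that("first stage handles exact and degenerate cases", {
  x <- rnorm(30)
  fs <- fit_first_stage(cbind(x), x)
  expect_equal(unname(fs$beta_hat), 1)
  expect_equal(fs$residual_exposure, rep(0, 30))
  set.seed(2)
  G <- cbind(a = rnorm(30), b = rnorm(30))
  x_orth <- residuals(lm(rnorm(30) ~ G))
  expect_lt(max(abs(fit_first_stage(G, x_orth)$beta_hat)), 1e-10)
  expect_error(fit_first_stage(cbind(G, G[, 1]), rnorm(30)), "rank")
  expect_error(fit_first_stage(matrix(rnorm(4), 2), rnorm(2)), "n > m")
})

test_that("design matrix has the documented column layout", {
  x <- rnorm(40); xh <- 0.6 * x
  M <- build_design(x, xh, k = 1, l = 1)
  expect_identical(colnames(M), c("(Intercept)", "x^1", "cf^1"))
  expect_equal(M[, 3], x - xh)
  M2 <- build_design(x, xh, k = 2, l = 0)
  expect_identical(colnames(M2), c("(Intercept)", "x^1", "x^2"))
  expect_equal(M2[, 3], x^2)
  expect_equal(ncol(build_design(x, xh, 10, 10)), 21)
  expect_error(build_design(x, xh, k = 0, l = 1), "k")
})

test_that("unselected fit reproduces lm() coefficients, SEs and p values", {
  st <- small_settings(n = 800, m = 10, seed = 13)
  d <- simulate_dataset(st)
  fit <- polymr(d$exposure, d$outcome, d$genotypes, k = 2, l = 2,
                select = FALSE, reverse_filter = FALSE)
  # independent route: explicit standardization + lm on the same design
  xs <- as.numeric(standardize(d$exposure))
  ys <- as.numeric(standardize(d$outcome))
  e <- fit_first_stage(d$genotypes, xs)$residual_exposure
  ref <- lm(ys ~ xs + I(xs^2) + e + I(e^2))
  sref <- summary(ref)$coefficients
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(sref[, 2]), tolerance = 1e-8)
  expect_equal(unname(fit$pvalues), unname(sref[, 4]), tolerance = 1e-8)
  expect_equal(unname(vcov(fit)), unname(vcov(ref)), tolerance = 1e-8)
  # second-stage residuals orthogonal to all design columns
  M <- model.matrix(ref)
  expect_lt(max(abs(crossprod(M, residuals(fit)))), 1e-6)
})

test_that("k = l = 1 equals the two-stage least-squares slope", {
  st <- small_settings(n = 600, m = 8, seed = 17)
  d <- simulate_dataset(st)
  fit <- polymr(d$exposure, d$outcome, d$genotypes, k = 1, l = 1,
                select = FALSE, reverse_filter = FALSE)
  xs <- as.numeric(standardize(d$exposure))
  ys <- as.numeric(standardize(d$outcome))
  xhat <- fitted(lm(xs ~ d$genotypes))
  tsls_slope <- coef(lm(ys ~ xhat))[2]
  expect_equal(unname(coef(fit)["x^1"]), unname(tsls_slope),
               tolerance = 1e-8)
})

test_that("non-linearity LRT matches the Gaussian closed form", {
  st <- small_settings(n = 500, m = 8, seed = 23)
  d <- simulate_dataset(st)
  fit <- polymr(d$exposure, d$outcome, d$genotypes, k = 2, l = 2,
                select = FALSE, reverse_filter = FALSE)
  xs <- as.numeric(standardize(d$exposure))
  ys <- as.numeric(standardize(d$outcome))
  e <- fit_first_stage(d$genotypes, xs)$residual_exposure
  rss_full <- sum(residuals(lm(ys ~ xs + I(xs^2) + e + I(e^2)))^2)
  rss_lin <- sum(residuals(lm(ys ~ xs + e + I(e^2)))^2)
  n <- length(ys)
  stat_oracle <- n * log(rss_lin / rss_full)
  expect_equal(2 * (fit$loglik_full - fit$loglik_linear), stat_oracle,
               tolerance = 1e-8)
  expect_equal(fit$nonlinearity_p, pchisq(stat_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("LRT p value is 1 when only the linear term remains", {
  st <- small_settings(n = 3000, m = 20, seed = 29,
                       causal_function = causal_fun("polynomial",
                                                    c(0, 0.1)))
  fit <- quick_fit(st)
  expect_identical(max(fit$k_retained), 1L)
  expect_identical(fit$nonlinearity_p, 1)
  expect_lt(fit$causal_r2, 0.05)
})

test_that("causally explained variance equals the r2 gain over confounding", {
  # independent route: r2 difference from two lm() fits on the same design
  r2_gain_oracle <- function(d, fit) {
    xs <- as.numeric(standardize(d$exposure))
    ys <- as.numeric(standardize(d$outcome))
    e <- fit_first_stage(
      scale(d$genotypes[, fit$iv$kept, drop = FALSE]), xs
    )$residual_exposure
    Mx <- sapply(fit$k_retained, function(j) xs^j)
    Me <- sapply(fit$l_retained, function(j) e^j)
    suppressWarnings(summary(lm(ys ~ Mx + Me))$r.squared -
                       summary(lm(ys ~ Me))$r.squared)
  }
  # deterministic outcome: full model is exact, gap is what the control
  # function cannot explain on its own
  set.seed(41)
  g <- simulate_genotypes(2000, 10)$genotypes
  b <- draw_effect_sizes(rep(0.25, 10), 0.5)
  x <- as.vector(g %*% b) + rnorm(2000, sd = sqrt(0.5))
  y <- 0.1 * x + 0.05 * x^2
  fit <- polymr(x, y, g, k = 2, l = 2, select = FALSE,
                reverse_filter = FALSE)
  expect_equal(fit$causal_r2,
               r2_gain_oracle(list(exposure = x, outcome = y,
                                   genotypes = g), fit),
               tolerance = 1e-8)
  expect_gt(fit$causal_r2, 0.3)
  # confounded quadratic scenario: same dual-route agreement, and the
  # causal contribution Var(0.1X + 0.05X^2)/Var(Y) = 0.015 bounds it
  st <- polymr_settings(n_samples = 30000, n_causal_snps = 50, seed = 43,
                        gwas_p_threshold = 1e-4)
  d <- simulate_dataset(st)
  ivs <- select_instruments(d)
  fit2 <- polymr(d$exposure, d$outcome, d$genotypes[, ivs, drop = FALSE])
  d$genotypes <- d$genotypes[, ivs, drop = FALSE]
  expect_equal(fit2$causal_r2, r2_gain_oracle(d, fit2), tolerance = 1e-6)
  expect_gt(fit2$causal_r2, 0.005)
  expect_lt(fit2$causal_r2, 0.02)
})

test_that("backward selection prunes a null quadratic model to linear", {
  st <- small_settings(n = 4000, m = 20, seed = 47, q_y2 = 0,
                       causal_function = causal_fun("polynomial", 0))
  fit <- quick_fit(st)
  expect_identical(fit$k_retained, 1L)
  expect_identical(fit$l_retained, 1L)
  expect_lt(fit$causal_r2, 0.01)
  # retained residual orders never exceed the highest exposure order
  expect_lte(max(fit$l_retained), max(fit$k_retained))
  # eliminated orders recorded with their p values
  expect_length(fit$selection_trace, 9)
  expect_true(all(vapply(fit$selection_trace, `[[`, 0, "p") >= 0.005))
})

test_that("coefficient covariance is symmetric PSD and matches retained set", {
  fit <- quick_fit(small_settings(n = 2000, m = 20, seed = 53))
  V <- vcov(fit)
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-12))
  expect_identical(nrow(V), length(coef(fit)))
  expect_true(fit$nonlinearity_p >= 0 && fit$nonlinearity_p <= 1)
  expect_true(fit$causal_r2 >= 0 && fit$causal_r2 <= 1)
})

test_that("reverse-causation filter applies the printed rule", {
  expect_identical(filter_reverse_ivs(c(0.1, 0.2, 0.05),
                                      c(0.05, 0.3, 0.01)), c(1L, 3L))
  expect_length(filter_reverse_ivs(0.05, 0.08), 0)     # removed
  expect_identical(filter_reverse_ivs(0.05, -0.05), 1L) # boundary kept
  expect_error(filter_reverse_ivs(c(0.1, 0.2), 0.1), "length")
})

test_that("causal curve is anchored at the mean exposure with valid hull", {
  fit <- quick_fit(small_settings(n = 2000, m = 20, seed = 59))
  cv <- predict(fit, grid = c(-2, -1, 0, 1, 2), n_draws = 2000, seed = 3)
  expect_equal(cv$estimate[3], 0)  # anchored at the mean (0 on SD scale)
  expect_true(all(cv$lower <= cv$estimate & cv$estimate <= cv$upper))
  # default grid: exposure percentiles 1-99
  cv2 <- predict(fit, n_draws = 200, seed = 3)
  expect_identical(nrow(cv2), 99L)
  # deterministic under a fixed seed
  expect_identical(predict(fit, n_draws = 500, seed = 11),
                   predict(fit, n_draws = 500, seed = 11))
  expect_error(predict(fit, n_draws = 10), "n_draws")
})

test_that("degenerate hulls and linear fits behave as expected", {
  fit <- quick_fit(small_settings(n = 2000, m = 20, seed = 61))
  fit$vcov[] <- 0
  cv <- predict(fit, grid = seq(-2, 2, 1), n_draws = 500, seed = 1)
  expect_equal(cv$lower, cv$estimate, tolerance = 1e-12)
  expect_equal(cv$upper, cv$estimate, tolerance = 1e-12)
  # linear-only fit predicts a straight line through (mean, 0)
  fit_lin <- quick_fit(small_settings(n = 3000, m = 20, seed = 29,
    causal_function = causal_fun("polynomial", c(0, 0.1))))
  g <- seq(-2, 2, 0.5)
  cv2 <- predict(fit_lin, grid = g, n_draws = 500, seed = 1)
  expect_equal(cv2$estimate, g * coef(fit_lin)["x^1"],
               ignore_attr = TRUE)
})

test_that("fits fail loudly on degenerate inputs", {
  d <- simulate_dataset(small_settings(n = 100, m = 5, seed = 67))
  expect_error(polymr(d$exposure, d$outcome, d$genotypes, k = 60, l = 60),
               "insufficient|n >")
  expect_error(polymr(rep(1, 100), d$outcome, d$genotypes), "constant")
  expect_error(polymr(d$exposure[1:50], d$outcome, d$genotypes),
               "matching")
})

test_that("incomplete rows are dropped with a logged count", {
  d <- simulate_dataset(small_settings(n = 500, m = 5, seed = 71))
  ex <- d$exposure; ex[c(3, 10)] <- NA
  expect_message(
    fit <- polymr(ex, d$outcome, d$genotypes, k = 2, l = 2),
    "2 incomplete")
  expect_identical(fit$n, 498L)
  expect_identical(fit$n_dropped, 2L)
})

test_that("summary and print surface the fit diagnostics", {
  fit <- quick_fit(small_settings(n = 2000, m = 20, seed = 73))
  s <- summary(fit)
  expect_s3_class(s, "summary.polymr")
  expect_true(all(c("Estimate", "Std. Error", "Pr(>|t|)") %in%
                    colnames(s$coefficients)))
  expect_output(print(fit), "retained exposure orders")
  expect_output(print(s), "Non-linearity LRT")
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik_full)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(dim(sims), c(fit$n, 2L))
})
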