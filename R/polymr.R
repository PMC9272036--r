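#' First-stage instrumental regression of exposure on genotypes
#'
#' Jointly regresses the exposure on all instruments by ordinary least
#' squares (never through an explicit matrix inverse: a Cholesky solve of
#' the Gram system when it is well-conditioned, a rank-revealing QR
#' decomposition otherwise), returning the genetic effect estimates, the
#' genetically predicted exposure, and the exposure residual that serves as
#' the control-function variable.
#'
#' @param G Numeric matrix of instruments (n x m), columns linearly
#'   independent, n > m.
#' @param x Exposure vector of length n.
#' @return An object of class `polymr_first_stage`: a list with `beta_hat`,
#'   `fitted_exposure` and `residual_exposure` (which sum to `x`
#'   elementwise).
#' @examples
#' G <- cbind(a = rnorm(50), b = rnorm(50))
#' f <- fit_first_stage(G, G[, 1] * 0.5 + rnorm(50))
#' f$beta_hat
#' @export
fit_first_stage <- function(G, x) {
  G <- as.matrix(G)
  n <- nrow(G); m <- ncol(G)
  if (m < 1L) stop("empty instrument set", call. = FALSE)
  if (length(x) != n)
    stop("`x` length must match nrow(G)", call. = FALSE)
  if (n <= m)
    stop("need more samples than instruments (n > m)", call. = FALSE)
  # Solve the joint least-squares problem. For well-conditioned instrument
  # sets (the norm for LD-pruned variants) the Gram/Cholesky route is exact
  # to machine precision and much faster at biobank n; ill-conditioned
  # inputs fall back to a rank-revealing QR decomposition.
  beta <- NULL
  R <- tryCatch(chol(crossprod(G)), error = function(e) NULL)
  if (!is.null(R) && kappa(R, exact = FALSE) < 1e4)
    beta <- backsolve(R, forwardsolve(t(R), as.vector(crossprod(G, x))))
  if (is.null(beta)) {
    qg <- qr(G)
    if (qg$rank < m) {
      cn <- colnames(G)
      if (is.null(cn)) cn <- paste0("IV", seq_len(m))
      bad <- cn[qg$pivot[(qg$rank + 1L):m]]
      stop("instrument matrix is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    beta <- qr.coef(qg, x)
  }
  names(beta) <- colnames(G)
  fitted <- as.vector(G %*% beta)
  structure(list(beta_hat = beta, fitted_exposure = fitted,
                 residual_exposure = x - fitted),
            class = "polymr_first_stage")
}

#' Build the second-stage polynomial control-function design matrix
#'
#' Columns are ordered as intercept, exposure powers
#' \eqn{x, \ldots, x^k}, then control-function powers
#' \eqn{(x - \hat{x})^1, \ldots, (x - \hat{x})^l} where
#' \eqn{\hat{x}} is the genetically predicted exposure. With k = l = 1 this
#' is the standard control-function design.
#'
#' @param x Exposure vector.
#' @param fitted_exposure Genetically predicted exposure (same length).
#' @param k Highest exposure power (>= 1; the linear term is the model
#'   floor).
#' @param l Highest control-function power (>= 0).
#' @return Numeric matrix with `1 + k + l` named columns.
#' @examples
#' x <- rnorm(20)
#' colnames(build_design(x, 0.7 * x, k = 2, l = 1))
#' @export
build_design <- function(x, fitted_exposure, k, l) {
  k <- as.integer(k); l <- as.integer(l)
  if (is.na(k) || k < 1L)
    stop("`k` must be >= 1 (the linear term is the model floor)",
         call. = FALSE)
  if (is.na(l) || l < 0L) stop("`l` must be >= 0", call. = FALSE)
  if (length(x) != length(fitted_exposure))
    stop("`x` and `fitted_exposure` lengths differ", call. = FALSE)
  e <- x - fitted_exposure
  M <- cbind(1, power_basis(x, k),
             if (l > 0L) power_basis(e, l))
  colnames(M) <- c("(Intercept)", paste0("x^", seq_len(k)),
                   if (l > 0L) paste0("cf^", seq_len(l)))
  M
}

# n x k matrix of powers v, v^2, ..., v^k by cumulative multiplication.
power_basis <- function(v, k) {
  P <- matrix(0, length(v), k)
  P[, 1] <- v
  if (k > 1L) for (j in 2:k) P[, j] <- P[, j - 1L] * v
  P
}

#' Keep instruments whose standardized effect is stronger on the exposure
#'
#' Reverse-causation filter: an instrument whose standardized marginal
#' effect is larger in absolute value on the outcome than on the exposure is
#' more plausibly acting through the outcome, and is removed. The boundary
#' (equal absolute effects) is retained.
#'
#' @param std_beta_exposure,std_beta_outcome Equal-length vectors of
#'   marginal simple-regression slopes on standardized traits.
#' @return Integer vector of retained indices.
#' @examples
#' filter_reverse_ivs(c(0.1, 0.2, 0.05), c(0.05, 0.3, 0.01))
#' @export
filter_reverse_ivs <- function(std_beta_exposure, std_beta_outcome) {
  if (length(std_beta_exposure) != length(std_beta_outcome))
    stop("effect vectors must have equal length", call. = FALSE)
  which(abs(std_beta_outcome) <= abs(std_beta_exposure))
}

#' Fit a polynomial Mendelian randomization model
#'
#' Estimates a polynomial approximation of the causal function of a
#' continuous exposure on a continuous outcome, using individual-level
#' genotypes as instruments. The model is fit in two ordinary-least-squares
#' stages: the exposure is regressed on all instruments jointly, and the
#' outcome is then regressed on exposure powers \eqn{x^1, \ldots, x^k}
#' together with powers of the first-stage residual
#' \eqn{(x - \hat{x})^1, \ldots, (x - \hat{x})^l} (the polynomial control
#' function), which absorb confounding and reverse causation. Exposure and
#' outcome are standardized internally, so coefficients are reported per
#' standard deviation of both traits.
#'
#' With `select = TRUE` (default), exposure coefficients of order >= 2 that
#' are not significant at the Bonferroni-corrected level `alpha_level / k`
#' are eliminated backwards, one at a time (least significant first),
#' truncating control-function powers to the highest surviving exposure
#' order after each step; the intercept and the linear term are never
#' candidates. A likelihood-ratio test against the linear model (keeping
#' the retained control-function terms) yields the non-linearity p value,
#' and the causally explained variance is the \eqn{r^2} gain of the full
#' model over the model with all exposure powers removed.
#'
#' `polymr_l1()` restricts the control function to first order (`l = 1`),
#' the standard control-function baseline; it is vulnerable to non-linear
#' confounding that the full model absorbs.
#'
#' @param exposure,outcome Numeric vectors of length n.
#' @param genotypes n x m numeric matrix of instrument dosages (any scale;
#'   standardized internally).
#' @param k Highest exposure power (default 10).
#' @param l Highest control-function power (default `k`).
#' @param select Apply backward elimination of non-significant exposure
#'   powers? (default `TRUE`)
#' @param alpha_level Significance level before Bonferroni correction by the
#'   initial `k` (default 0.05, i.e. per-coefficient threshold 0.005 at
#'   k = 10).
#' @param reverse_filter Remove instruments whose standardized marginal
#'   effect is larger on the outcome than on the exposure? (default `TRUE`)
#' @param truncate_residual Truncate control-function powers to the highest
#'   retained exposure order during selection? (default `TRUE`; forced off
#'   only makes a difference when `l` exceeds the final exposure order.)
#' @param robust Also compute a heteroskedasticity-robust (HC0) coefficient
#'   covariance, stored as `vcov_robust`? Classical OLS covariance remains
#'   the default used for inference. (default `FALSE`)
#' @return An object of class `polymr`. Key components: `alpha_hat` (named
#'   by order, intercept = order 0), `r_hat` (control-function
#'   coefficients), `coefficients`, `vcov`, `se`, `pvalues`,
#'   `nonlinearity_p`, `causal_r2`, `loglik_full`, `loglik_linear`,
#'   `selection_trace`, `first_stage`, `residuals` (second-stage residual
#'   noise), `n`, `iv` (instrument bookkeeping), and the standardization
#'   constants of both traits. Methods: [print.polymr()],
#'   [summary.polymr()], [coef.polymr()], [vcov.polymr()],
#'   [predict.polymr()], [plot.polymr()], `residuals()`, `fitted()`,
#'   `logLik()`, [simulate.polymr()].
#' @examples
#' set.seed(1)
#' g <- simulate_genotypes(800, 8)$genotypes
#' b <- draw_effect_sizes(rep(0.2, 8), 0.4)
#' x <- as.vector(g %*% b) + rnorm(800, sd = sqrt(0.6))
#' y <- 0.2 * x + 0.1 * x^2 + rnorm(800)
#' fit <- polymr(x, y, g, k = 3)
#' coef(fit)
#' @export
polymr <- function(exposure, outcome, genotypes, k = 10, l = k,
                   select = TRUE, alpha_level = 0.05,
                   reverse_filter = TRUE, truncate_residual = TRUE,
                   robust = FALSE) {
  cl <- match.call()
  G <- as.matrix(genotypes)
  if (is.null(colnames(G))) colnames(G) <- paste0("IV", seq_len(ncol(G)))
  n0 <- length(exposure)
  if (length(outcome) != n0 || nrow(G) != n0)
    stop("`exposure`, `outcome` and `genotypes` must have matching rows",
         call. = FALSE)
  k <- as.integer(k); l <- as.integer(l)
  if (is.na(k) || k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (is.na(l) || l < 0L) stop("`l` must be >= 0", call. = FALSE)

  n_dropped <- 0L
  if (anyNA(exposure) || anyNA(outcome) || anyNA(G)) {
    cc <- stats::complete.cases(exposure, outcome, G)
    n_dropped <- sum(!cc)
  }
  if (n_dropped > 0L) {
    message("dropping ", n_dropped, " incomplete row(s); ", sum(cc),
            " complete cases used")
    exposure <- exposure[cc]; outcome <- outcome[cc]
    G <- G[cc, , drop = FALSE]
  }
  n <- length(exposure)
  if (n <= 1L + k + l)
    stop("insufficient sample: need n > 1 + k + l design columns",
         call. = FALSE)

  xs <- standardize(exposure)
  ys <- standardize(outcome)
  x_center <- attr(xs, "center"); x_scale <- attr(xs, "scale")
  y_center <- attr(ys, "center"); y_scale <- attr(ys, "scale")
  xs <- as.numeric(xs); ys <- as.numeric(ys)

  cm <- colMeans(G)
  csd <- sqrt((colSums(G^2) - n * cm^2) / (n - 1))
  if (any(!is.finite(csd) | csd == 0))
    stop("constant genotype column(s): ",
         paste(colnames(G)[!is.finite(csd) | csd == 0], collapse = ", "),
         call. = FALSE)
  if (max(abs(cm)) < 1e-12 && max(abs(csd - 1)) < 1e-12) {
    Gs <- G  # already standardized (e.g. simulator output)
  } else {
    Gs <- (G - rep(cm, each = n)) * rep(1 / csd, each = n)
    colnames(Gs) <- colnames(G)
  }

  m_initial <- ncol(Gs)
  if (reverse_filter) {
    keep <- filter_reverse_ivs(marginal_std_slopes(Gs, xs),
                               marginal_std_slopes(Gs, ys))
    if (length(keep) == 0L)
      stop("reverse-causation filter removed every instrument",
           call. = FALSE)
    Gs <- Gs[, keep, drop = FALSE]
  } else {
    keep <- seq_len(m_initial)
  }

  fs <- fit_first_stage(Gs, xs)
  e <- fs$residual_exposure

  XP <- power_basis(xs, k)
  EP <- if (l > 0L) power_basis(e, l) else NULL
  cache <- build_cache(XP, EP, ys)
  sel <- backward_select(cache, k, l, select, alpha_level,
                         truncate_residual)

  fin <- final_ols(XP, EP, ys, sel$expo, sel$resid, robust)

  # Non-linearity LRT: exposure powers restricted to {1}, control-function
  # columns frozen at the retained orders.
  df_nl <- sum(sel$expo >= 2L)
  rss_lin <- cache_rss(cache, c(1L, if (l > 0L) k + sel$resid))
  ll_full <- gauss_loglik(fin$rss, n)
  ll_lin <- gauss_loglik(rss_lin, n)
  nonlinearity_p <- if (df_nl == 0L) 1 else
    stats::pchisq(2 * (ll_full - ll_lin), df = df_nl, lower.tail = FALSE)

  # Causally explained variance: r^2 gain over the confounding-only model.
  rss_conf <- cache_rss(cache, if (l > 0L) k + sel$resid else integer(0))
  tss <- sum((ys - mean(ys))^2)
  causal_r2 <- max(0, (rss_conf - fin$rss) / tss)

  a_names <- paste0("x^", sel$expo)
  alpha_hat <- c(fin$coef["(Intercept)"], fin$coef[a_names])
  names(alpha_hat) <- c("0", sel$expo)
  r_hat <- fin$coef[paste0("cf^", sel$resid)]
  names(r_hat) <- sel$resid

  structure(list(
    call = cl, coefficients = fin$coef, alpha_hat = alpha_hat,
    r_hat = r_hat, vcov = fin$vcov, se = fin$se, pvalues = fin$pvalues,
    vcov_robust = fin$vcov_robust,
    k = k, l = l, k_retained = sel$expo, l_retained = sel$resid,
    select = select, alpha_level = alpha_level,
    nonlinearity_p = nonlinearity_p, causal_r2 = causal_r2,
    loglik_full = ll_full, loglik_linear = ll_lin,
    selection_trace = sel$trace, sigma2 = fin$sigma2,
    residuals = fin$residuals, fitted.values = fin$fitted,
    condition_number = fin$condition, n = n, n_dropped = n_dropped,
    iv = list(n_initial = m_initial, n_used = length(keep), kept = keep,
              reverse_filter = reverse_filter),
    first_stage = fs,
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    exposure_std = xs), class = "polymr")
}

#' @rdname polymr
#' @param ... Arguments passed on to `polymr()`.
#' @export
polymr_l1 <- function(exposure, outcome, genotypes, ...) {
  polymr(exposure, outcome, genotypes, l = 1L, truncate_residual = FALSE,
         ...)
}

# Cached cross-products of the centered/scaled power design. Centering and
# per-column scaling leave non-intercept coefficients' t statistics and the
# fit of any intercept-containing submodel unchanged, while conditioning the
# moment matrix far better than raw powers would.
build_cache <- function(XP, EP, ys) {
  n <- length(ys)
  D <- cbind(XP, EP)
  cm <- colMeans(D)
  cs <- sqrt(colSums(D^2) / n - cm^2)
  cs[cs == 0] <- 1
  Dc <- (D - rep(cm, each = n)) * rep(1 / cs, each = n)
  yc <- ys - mean(ys)
  list(C = crossprod(Dc), Cty = as.vector(crossprod(Dc, yc)),
       yty = sum(yc^2), n = n)
}

# Residual sum of squares of the submodel [intercept, selected columns],
# solved from the cached moment matrix.
cache_rss <- function(cache, cols) {
  if (length(cols) == 0L) return(cache$yty)
  Cs <- cache$C[cols, cols, drop = FALSE]
  R <- tryCatch(chol(Cs), error = function(e) NULL)
  if (is.null(R))
    stop("second-stage design is numerically singular ",
         "(near-constant exposure?)", call. = FALSE)
  b <- backsolve(R, forwardsolve(t(R), cache$Cty[cols]))
  max(cache$yty - sum(b * (2 * cache$Cty[cols] -
                             Cs %*% b)), 0)
}

# Backward elimination on the cached cross-product: each step is O(p^3)
# instead of O(n p^2).
backward_select <- function(cache, k, l, select, alpha_level,
                            truncate_residual) {
  expo <- seq_len(k)
  resid <- seq_len(l)
  trace <- list()
  if (!select || k < 2L)
    return(list(expo = expo, resid = resid, trace = trace))
  n <- cache$n
  thr <- alpha_level / k

  repeat {
    cols <- c(expo, if (l > 0L) k + resid)
    p <- length(cols) + 1L  # + intercept
    Cs <- cache$C[cols, cols, drop = FALSE]
    R <- tryCatch(chol(Cs), error = function(e) NULL)
    if (is.null(R))
      stop("second-stage design is numerically singular ",
           "(near-constant exposure?)", call. = FALSE)
    b <- backsolve(R, forwardsolve(t(R), cache$Cty[cols]))
    rss <- cache$yty - sum(b * (2 * cache$Cty[cols] - Cs %*% b))
    sigma2 <- max(rss, 0) / (n - p)
    inv <- chol2inv(R)
    se <- sqrt(sigma2 * diag(inv))
    pv <- 2 * stats::pt(-abs(b / se), df = n - p)
    cand <- which(expo >= 2L)
    if (length(cand) == 0L) break
    pv_expo <- pv[seq_along(expo)][cand]
    worst <- which(pv_expo >= thr)
    if (length(worst) == 0L) break
    # Among the non-significant exposure coefficients, remove the highest
    # order first (marginality: high-order terms are least interpretable
    # and most collinear with the rest of the basis), then refit.
    drop_i <- cand[worst[which.max(expo[cand[worst]])]]
    trace[[length(trace) + 1L]] <-
      list(order = expo[drop_i], p = pv_expo[match(drop_i, cand)])
    expo <- expo[-drop_i]
    if (truncate_residual && l > 0L)
      resid <- resid[resid <= max(expo)]
  }
  list(expo = expo, resid = resid, trace = trace)
}

# Final OLS fit by QR on the raw (uncentered) design for the retained
# exposure and control-function orders.
final_ols <- function(XP, EP, ys, expo, resid, robust) {
  n <- length(ys)
  M <- cbind(`(Intercept)` = rep(1, n),
             XP[, expo, drop = FALSE],
             if (length(resid) > 0L) EP[, resid, drop = FALSE])
  colnames(M) <- c("(Intercept)",
                   if (length(expo) > 0L) paste0("x^", expo),
                   if (length(resid) > 0L) paste0("cf^", resid))
  p <- ncol(M)
  qf <- qr(M)
  if (qf$rank < p)
    stop("second-stage design is rank deficient (collinear columns: ",
         paste(colnames(M)[qf$pivot[(qf$rank + 1L):p]], collapse = ", "),
         ")", call. = FALSE)
  b <- qr.coef(qf, ys)
  fitted <- as.vector(M %*% b)
  r <- ys - fitted
  rss <- sum(r^2)
  sigma2 <- rss / (n - p)
  R <- qr.R(qf)
  piv <- qf$pivot
  inv <- matrix(0, p, p)
  inv[piv, piv] <- chol2inv(R)
  V <- sigma2 * inv
  dimnames(V) <- list(colnames(M), colnames(M))
  se <- sqrt(diag(V))
  pv <- 2 * stats::pt(-abs(b / se), df = n - p)
  # Collinearity diagnostic on the column-normalized design (scale-free).
  cn <- sqrt(colSums(M^2))
  condition <- kappa(R %*% diag(1 / cn[piv], p), exact = FALSE)
  if (condition > 1e8)
    warning("second-stage design condition number exceeds 1e8; ",
            "estimates may be numerically unstable", call. = FALSE)
  Vr <- NULL
  if (robust) {
    meat <- crossprod(M * r)
    Vr <- inv %*% meat %*% inv
    dimnames(Vr) <- dimnames(V)
  }
  list(coef = b, vcov = V, se = se, pvalues = pv, sigma2 = sigma2,
       rss = rss, residuals = r, fitted = fitted, condition = condition,
       vcov_robust = Vr)
}

# Gaussian log-likelihood with the error variance profiled out.
gauss_loglik <- function(rss, n) -n / 2 * (log(2 * pi * rss / n) + 1)
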