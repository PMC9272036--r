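#' Simulate standardized genotype dosages
#'
#' Draws minor allele frequencies from a Beta(1, 3) distribution (rejected
#' until they fall in `maf_range`, keeping "minor"-allele semantics and
#' avoiding near-monomorphic variants), draws raw allele dosages from
#' Binomial(2, p), and standardizes each column to sample mean 0 and sample
#' variance 1. Columns that come out monomorphic in-sample (possible at
#' small `n`) are redrawn with a fresh frequency.
#'
#' @param n Number of individuals (>= 2).
#' @param m Number of variants (>= 1).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param maf_range Admissible minor-allele-frequency interval.
#' @return A list with `genotypes` (an `n` x `m` standardized dosage matrix)
#'   and `mafs` (the `m` allele frequencies).
#' @examples
#' g <- simulate_genotypes(200, 5, seed = 1)
#' colMeans(g$genotypes)
#' @export
simulate_genotypes <- function(n, m, seed = NULL, maf_range = c(0.01, 0.5)) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || n < 2L) stop("`n` must be >= 2", call. = FALSE)
  if (is.na(m) || m < 1L) stop("`m` must be >= 1", call. = FALSE)
  with_seed(seed, {
    mafs <- draw_mafs(m, maf_range)
    G <- matrix(stats::rbinom(n * m, 2L, rep(mafs, each = n)), n, m)
    repeat {
      cm <- colMeans(G)
      csd <- sqrt((colSums(G * G) - n * cm^2) / (n - 1))
      bad <- which(!is.finite(csd) | csd == 0)
      if (length(bad) == 0L) break
      mafs[bad] <- draw_mafs(length(bad), maf_range)
      G[, bad] <- stats::rbinom(n * length(bad), 2L,
                                rep(mafs[bad], each = n))
    }
    G <- (G - rep(cm, each = n)) * rep(1 / csd, each = n)
    list(genotypes = G, mafs = mafs)
  })
}

draw_mafs <- function(m, maf_range) {
  p <- numeric(m)
  todo <- seq_len(m)
  while (length(todo) > 0L) {
    p[todo] <- stats::rbeta(length(todo), 1, 3)
    todo <- todo[p[todo] < maf_range[1] | p[todo] > maf_range[2]]
  }
  p
}

#' Draw per-variant genetic effect sizes
#'
#' Effects are drawn as \eqn{\beta_i \sim N(0, (p_i (1 - p_i))^{-0.25})}
#' (an allele-frequency-dependent architecture in which rarer variants have
#' larger per-allele effects on the standardized scale) and then rescaled so
#' that the variants jointly explain exactly `h2` of the exposure variance,
#' i.e. \eqn{\sum_i \beta_i^2 = h^2}.
#'
#' @param mafs Vector of minor allele frequencies in (0, 0.5].
#' @param h2 Target heritability in (0, 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of effect sizes with `sum(beta^2) == h2`.
#' @examples
#' b <- draw_effect_sizes(c(0.1, 0.2, 0.3), 0.5, seed = 1)
#' sum(b^2)
#' @export
draw_effect_sizes <- function(mafs, h2, seed = NULL) {
  if (length(mafs) == 0L) stop("`mafs` must be non-empty", call. = FALSE)
  if (any(mafs <= 0 | mafs > 0.5))
    stop("`mafs` must lie in (0, 0.5]", call. = FALSE)
  if (h2 <= 0 || h2 >= 1) stop("`h2` must be in (0, 1)", call. = FALSE)
  with_seed(seed, {
    beta <- stats::rnorm(length(mafs),
                         sd = (mafs * (1 - mafs))^(-0.125))
    beta * sqrt(h2 / sum(beta^2))
  })
}

#' Simulate a genotype-exposure-outcome dataset
#'
#' Generates data under the confounded generative model described in
#' [polymr_settings()]: standardized genotypes, a shared standard-normal
#' confounder \eqn{U} entering the exposure linearly and the outcome
#' linearly and quadratically, and an arbitrary causal function of the
#' exposure. The exposure noise variance is set to
#' \eqn{1 - h^2 - q_x^2} so \eqn{Var(X) = 1} in expectation, and the
#' exposure is then empirically re-standardized before the causal function
#' is applied, so the causal coefficients act on an exactly unit-variance
#' exposure. The outcome noise variance is set to the complement of the
#' realized signal variance (causal + confounder contributions) so that
#' \eqn{Var(Y) = 1} by construction; the outcome is then empirically
#' standardized (the raw outcome is retained as `outcome_raw`).
#'
#' @param settings A [polymr_settings()] object.
#' @return An object of class `polymr_sim`: a list with the standardized
#'   `genotypes`, `mafs`, `true_beta` (rescaled so `sum(true_beta^2)` equals
#'   the heritability), `confounder`, `exposure` (raw scale,
#'   `G %*% beta + q_x U + eps_x` exactly), `exposure_std`, `outcome`
#'   (standardized), `outcome_raw`, `exposure_noise`, `outcome_noise`, and
#'   the `settings` echo.
#' @examples
#' d <- simulate_dataset(polymr_settings(n_samples = 500, n_causal_snps = 10,
#'                                       seed = 1))
#' var(d$exposure_std)
#' @export
simulate_dataset <- function(settings) {
  if (!inherits(settings, "polymr_settings"))
    stop("`settings` must be built with polymr_settings()", call. = FALSE)
  n <- settings$n_samples
  m <- settings$n_causal_snps
  h2 <- settings$heritability
  ss <- derive_seeds(settings$seed, 5L)

  gen <- simulate_genotypes(n, m, seed = ss[1])
  beta <- draw_effect_sizes(gen$mafs, h2, seed = ss[2])
  U <- with_seed(ss[3], stats::rnorm(n))
  eps_x <- with_seed(ss[4],
    stats::rnorm(n, sd = sqrt(1 - h2 - settings$q_x^2)))
  x <- as.vector(gen$genotypes %*% beta) + settings$q_x * U + eps_x
  xs <- standardize(x)

  signal <- evaluate_causal_function(settings$causal_function,
                                     as.numeric(xs)) +
    settings$q_y * U + settings$q_y2 * U^2
  v_eps <- 1 - stats::var(signal)
  if (v_eps < 0.05) {
    warning("signal variance exceeds 0.95; outcome noise variance floored ",
            "at 0.05 so Var(Y) > 1", call. = FALSE)
    v_eps <- 0.05
  }
  eps_y <- with_seed(ss[5], stats::rnorm(n, sd = sqrt(v_eps)))
  y <- signal + eps_y
  ys <- standardize(y)

  structure(list(genotypes = gen$genotypes, mafs = gen$mafs,
                 true_beta = beta, confounder = U, exposure = x,
                 exposure_std = as.numeric(xs), outcome = as.numeric(ys),
                 outcome_raw = y, exposure_noise = eps_x,
                 outcome_noise = eps_y, settings = settings),
            class = "polymr_sim")
}

#' @export
print.polymr_sim <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d samples x %d causal SNPs\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  var(exposure) = %.4f, var(outcome) = %.4f, ",
              stats::var(x$exposure), stats::var(x$outcome)))
  cat(sprintf("sum(beta^2) = %.4f\n", sum(x$true_beta^2)))
  print(x$settings)
  invisible(x)
}

#' Select instruments by marginal genome-wide significance
#'
#' For each variant, tests the marginal simple-regression association of the
#' exposure on that variant (classical two-sided t test) and retains the
#' variants with p below `p_threshold`, preserving column order. This
#' mirrors instrument selection from a GWAS of the exposure in the same
#' sample.
#'
#' @param object A `polymr_sim` dataset or a numeric genotype matrix.
#' @param exposure Exposure vector (ignored when `object` is a dataset).
#' @param p_threshold Two-sided p-value threshold; defaults to the dataset's
#'   `gwas_p_threshold` (5e-8 otherwise).
#' @return Integer vector of retained column indices (possibly empty).
#' @examples
#' d <- simulate_dataset(polymr_settings(n_samples = 500, n_causal_snps = 10,
#'                                       heritability = 0.6, seed = 1))
#' select_instruments(d, p_threshold = 1e-3)
#' @export
select_instruments <- function(object, exposure = NULL, p_threshold = NULL) {
  if (inherits(object, "polymr_sim")) {
    G <- object$genotypes
    exposure <- object$exposure
    if (is.null(p_threshold)) p_threshold <- object$settings$gwas_p_threshold
  } else {
    G <- as.matrix(object)
    if (is.null(exposure)) stop("`exposure` is required", call. = FALSE)
    if (is.null(p_threshold)) p_threshold <- 5e-8
  }
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("`p_threshold` must lie strictly between 0 and 1", call. = FALSE)
  n <- nrow(G)
  if (length(exposure) != n)
    stop("`exposure` length must match nrow(genotypes)", call. = FALSE)
  as.integer(which(marginal_pvalues(G, exposure) < p_threshold))
}

# Column correlations with y without materializing a centered copy of G:
# since y is centered first, crossprod(G, yc) equals crossprod(Gc, yc).
col_cors <- function(G, y) {
  n <- nrow(G)
  yc <- y - mean(y)
  cm <- colMeans(G)
  css <- colSums(G^2) - n * cm^2
  r <- as.vector(crossprod(G, yc)) / sqrt(css * sum(yc^2))
  pmin(pmax(r, -1), 1)
}

# Two-sided p values of marginal simple regressions of `y` on each column
# of `G`, via the correlation form of the t statistic.
marginal_pvalues <- function(G, y) {
  n <- nrow(G)
  r <- col_cors(G, y)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}

# Marginal simple-regression slopes of standardized `y` on standardized
# genotype columns (equal to the correlations).
marginal_std_slopes <- function(G, y) col_cors(G, y)
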