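#' Simulation settings for genotype-exposure-outcome data
#'
#' Collects every generative parameter of the simulator into a validated
#' settings object. The generative model is
#' \deqn{X = G\beta + q_x U + \epsilon_x, \qquad
#'       Y = f(X) + q_y U + q_{y2} U^2 + \epsilon_y,}
#' where \eqn{U} is a standard-normal confounder shared by exposure and
#' outcome, \eqn{G} holds standardized allele dosages of `n_causal_snps`
#' causal variants jointly explaining `heritability` of the exposure
#' variance, and both traits are constructed to zero mean and unit variance.
#'
#' @param n_samples Number of individuals (\eqn{n \ge 2}).
#' @param n_causal_snps Number of causal variants (\eqn{m \ge 1}).
#' @param heritability Fraction of exposure variance explained by the causal
#'   variants in aggregate (\eqn{0 < h^2 < 1}).
#' @param q_x Confounder weight on the exposure. `heritability + q_x^2` must
#'   be below 1 so the exposure noise variance stays positive.
#' @param q_y Linear confounder weight on the outcome.
#' @param q_y2 Quadratic confounder weight on the outcome.
#' @param causal_function A [causal_fun()] object; the true causal effect of
#'   the (standardized) exposure on the outcome.
#' @param gwas_p_threshold Two-sided p-value threshold for marginal
#'   instrument selection (genome-wide significance, default `5e-8`).
#' @param seed Integer master seed. All random components derive independent
#'   sub-streams from it, so a dataset regenerates bit-for-bit. If `NULL`, a
#'   seed is drawn and recorded.
#'
#' @return An object of class `polymr_settings`.
#' @seealso [simulate_dataset()], [polymr_scenarios()]
#' @examples
#' st <- polymr_settings(n_samples = 1000, n_causal_snps = 20, seed = 7)
#' st
#' @export
polymr_settings <- function(n_samples = 1e5L, n_causal_snps = 100L,
                            heritability = 0.5, q_x = 0.2, q_y = 0.5,
                            q_y2 = 0,
                            causal_function = causal_fun("polynomial",
                                                         c(0, 0.1, 0.05)),
                            gwas_p_threshold = 5e-8, seed = NULL) {
  n_samples <- as.integer(n_samples)
  n_causal_snps <- as.integer(n_causal_snps)
  if (is.na(n_samples) || n_samples < 2L)
    stop("`n_samples` must be an integer >= 2", call. = FALSE)
  if (is.na(n_causal_snps) || n_causal_snps < 1L)
    stop("`n_causal_snps` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(heritability) || heritability <= 0 || heritability >= 1)
    stop("`heritability` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(q_x) || !is.finite(q_x) || !is.finite(q_y) ||
      !is.finite(q_y2))
    stop("confounder weights must be finite numbers", call. = FALSE)
  if (heritability + q_x^2 >= 1)
    stop("`heritability` + `q_x`^2 must be < 1 ",
         "(exposure noise variance must be positive)", call. = FALSE)
  if (!inherits(causal_function, "causal_fun"))
    stop("`causal_function` must be built with causal_fun()", call. = FALSE)
  if (!is.numeric(gwas_p_threshold) || gwas_p_threshold <= 0 ||
      gwas_p_threshold >= 1)
    stop("`gwas_p_threshold` must lie strictly between 0 and 1",
         call. = FALSE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be coercible to integer", call. = FALSE)
  structure(list(n_samples = n_samples, n_causal_snps = n_causal_snps,
                 heritability = heritability, q_x = q_x, q_y = q_y,
                 q_y2 = q_y2, causal_function = causal_function,
                 gwas_p_threshold = gwas_p_threshold, seed = seed),
            class = "polymr_settings")
}

#' @export
print.polymr_settings <- function(x, ...) {
  cat("Simulation settings\n")
  cat(sprintf("  n = %d samples, m = %d causal SNPs, h2 = %g\n",
              x$n_samples, x$n_causal_snps, x$heritability))
  cat(sprintf("  confounding: q_x = %g, q_y = %g, q_y2 = %g\n",
              x$q_x, x$q_y, x$q_y2))
  print(x$causal_function)
  cat(sprintf("  GWAS threshold = %g, seed = %d\n",
              x$gwas_p_threshold, x$seed))
  invisible(x)
}

#' Named simulation scenarios
#'
#' Returns the library of canonical simulation scenarios: thirteen causal
#' function shapes (quadratic base case, null, linear, stronger quadratic,
#' weak quadratic, cubic, fourth order, third-and-fourth order, exponential,
#' signed square root, and three sigmoids of increasing steepness) and the
#' confounding variations (strong, negative, quadratic with weight 0.1 or
#' 0.2, and quadratic confounding with a purely linear causal effect). All
#' scenarios default to the base parameters n = 100,000, m = 100 causal
#' SNPs, h2 = 0.5, q_x = 0.2, q_y = 0.5, q_y2 = 0.
#'
#' @param scenario Optional scenario name; if supplied, the corresponding
#'   settings object is returned directly.
#' @param ... Overrides passed on to [polymr_settings()] (for example
#'   `n_samples`, `heritability`, `seed`).
#' @return A named list of `polymr_settings` objects, or a single settings
#'   object if `scenario` is given.
#' @examples
#' names(polymr_scenarios())
#' polymr_scenarios("weak_quadratic", n_samples = 5000, seed = 1)
#' @export
polymr_scenarios <- function(scenario = NULL, ...) {
  poly <- function(...) causal_fun("polynomial", c(...))
  base_f <- poly(0, 0.1, 0.05)
  defs <- list(
    base = list(causal_function = base_f),
    null = list(causal_function = poly(0)),
    linear = list(causal_function = poly(0, 0.1)),
    stronger = list(causal_function = poly(0, 0.3, 0.1)),
    weak_quadratic = list(causal_function = poly(0, 0.1, 0.01)),
    cubic = list(causal_function = poly(0, 0.1, 0.05, 0.05)),
    fourth_order = list(causal_function = poly(0, 0.1, 0.05, 0, 0.05)),
    third_fourth = list(causal_function = poly(0, 0.1, 0.05, 0.03, 0.01)),
    exponential = list(causal_function = causal_fun("exponential",
                                                    scale = 0.1)),
    signed_sqrt = list(causal_function = causal_fun("signed_sqrt",
                                                    scale = 0.1)),
    sigmoid_1 = list(causal_function = causal_fun("sigmoid", scale = 0.1,
                                                  steepness = 1)),
    sigmoid_2 = list(causal_function = causal_fun("sigmoid", scale = 0.1,
                                                  steepness = 2)),
    sigmoid_3 = list(causal_function = causal_fun("sigmoid", scale = 0.1,
                                                  steepness = 3)),
    strong_confounding = list(causal_function = base_f, q_x = 0.5,
                              q_y = 0.8),
    negative_confounding = list(causal_function = base_f, q_y = -0.5),
    quadratic_confounding_0.1 = list(causal_function = base_f, q_y2 = 0.1),
    quadratic_confounding_0.2 = list(causal_function = base_f, q_y2 = 0.2),
    quadratic_confounding_linear = list(causal_function = poly(0, 0.1),
                                        q_y2 = 0.2)
  )
  overrides <- list(...)
  build <- function(d) do.call(polymr_settings, utils::modifyList(d, overrides))
  if (!is.null(scenario)) {
    if (!scenario %in% names(defs))
      stop("unknown scenario; available: ",
           paste(names(defs), collapse = ", "), call. = FALSE)
    return(build(defs[[scenario]]))
  }
  lapply(defs, build)
}
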