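#' Specify the true causal function of a simulation scenario
#'
#' Constructs a description of the causal function \eqn{f(\cdot)} mapping the
#' (standardized) exposure to its causal contribution to the outcome. Four
#' families are supported:
#' \describe{
#'   \item{`polynomial`}{\eqn{f(x) = \sum_j a_j x^j}, with `coefficients`
#'     giving \eqn{a_0, a_1, \ldots} in ascending order.}
#'   \item{`exponential`}{\eqn{f(x) = s\, e^{x}}.}
#'   \item{`signed_sqrt`}{\eqn{f(x) = s\, \mathrm{sgn}(x) \sqrt{|x|}}.}
#'   \item{`sigmoid`}{\eqn{f(x) = s / (1 + e^{-\theta x})}, with `steepness`
#'     \eqn{\theta}.}
#' }
#'
#' @param family One of `"polynomial"`, `"exponential"`, `"signed_sqrt"`,
#'   `"sigmoid"`.
#' @param coefficients Numeric vector of polynomial coefficients in ascending
#'   order of power (intercept first). Required for the polynomial family.
#' @param scale Prefactor \eqn{s} for the non-polynomial families.
#' @param steepness Exponent multiplier \eqn{\theta} for the sigmoid family.
#'
#' @return An object of class `causal_fun`.
#' @seealso [evaluate_causal_function()], [polymr_settings()]
#' @examples
#' f <- causal_fun("polynomial", coefficients = c(0, 0.1, 0.05))
#' evaluate_causal_function(f, c(-1, 0, 1))
#' @export
causal_fun <- function(family = c("polynomial", "exponential", "signed_sqrt",
                                  "sigmoid"),
                       coefficients = NULL, scale = 0.1, steepness = 1) {
  family <- match.arg(family)
  if (family == "polynomial") {
    if (is.null(coefficients) || length(coefficients) == 0L)
      stop("polynomial causal functions need a non-empty `coefficients` vector",
           call. = FALSE)
    if (!is.numeric(coefficients) || anyNA(coefficients))
      stop("`coefficients` must be numeric without missing values",
           call. = FALSE)
    coefficients <- as.numeric(coefficients)
  } else {
    if (!is.finite(scale)) stop("`scale` must be finite", call. = FALSE)
    if (family == "sigmoid" && (!is.finite(steepness) || steepness <= 0))
      stop("`steepness` must be a positive finite number", call. = FALSE)
  }
  structure(list(family = family, coefficients = coefficients,
                 scale = scale, steepness = steepness),
            class = "causal_fun")
}

#' Evaluate a causal function on a vector of exposure values
#'
#' @param spec A [causal_fun()] object.
#' @param x Numeric vector of exposure values (standardized scale).
#' @return Numeric vector `f(x)` of the same length as `x`. Polynomials are
#'   evaluated by Horner's scheme.
#' @examples
#' evaluate_causal_function(causal_fun("sigmoid", scale = 0.1, steepness = 2), 0)
#' @export
evaluate_causal_function <- function(spec, x) {
  if (!inherits(spec, "causal_fun"))
    stop("`spec` must be a `causal_fun` object", call. = FALSE)
  x <- as.numeric(x)
  switch(spec$family,
    polynomial = {
      a <- spec$coefficients
      out <- rep(a[length(a)], length(x))
      if (length(a) > 1L)
        for (j in rev(seq_len(length(a) - 1L))) out <- out * x + a[j]
      out
    },
    exponential = spec$scale * exp(x),
    signed_sqrt = spec$scale * sign(x) * sqrt(abs(x)),
    sigmoid = spec$scale / (1 + exp(-spec$steepness * x)),
    stop("unknown causal function family", call. = FALSE)
  )
}

#' @export
print.causal_fun <- function(x, ...) {
  if (x$family == "polynomial") {
    a <- x$coefficients
    pw <- seq_along(a) - 1L
    keep <- a != 0 | pw == 1L
    if (!any(keep)) keep <- 1L
    terms <- ifelse(pw[keep] == 0L, format(a[keep]),
                    paste0(format(a[keep]), "*x^", pw[keep]))
    cat("Causal function: f(x) =", paste(terms, collapse = " + "), "\n")
  } else {
    form <- switch(x$family,
      exponential = sprintf("%g * exp(x)", x$scale),
      signed_sqrt = sprintf("%g * sgn(x) * sqrt(|x|)", x$scale),
      sigmoid = sprintf("%g / (1 + exp(-%g * x))", x$scale, x$steepness))
    cat("Causal function: f(x) =", form, "\n")
  }
  invisible(x)
}
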