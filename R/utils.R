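# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seeds derived from a master seed, so independent random
# components (genotypes, effect sizes, noises, replicates) can be varied or
# reproduced independently. Values stay below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Standardize a numeric vector to zero mean and unit variance
#'
#' Centers and scales `v` to sample mean 0 and sample variance 1, recording
#' the original location and scale as attributes `center` and `scale` so the
#' transformation can be inverted.
#'
#' @param v Numeric vector with at least two distinct finite values.
#' @return The standardized vector, with attributes `center` and `scale`.
#' @examples
#' z <- standardize(c(1, 2, 3))
#' attr(z, "center"); attr(z, "scale")
#' @export
standardize <- function(v) {
  if (!is.numeric(v) || length(v) < 2L)
    stop("`v` must be a numeric vector of length >= 2", call. = FALSE)
  m <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant vector (zero variance)",
         call. = FALSE)
  out <- (v - m) / s
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

# Format numbers so text round trips reproduce IEEE doubles exactly.
fmt_num <- function(x) formatC(x, format = "g", digits = 17)
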