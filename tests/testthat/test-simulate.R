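test_that("genotype columns are standardized and MAFs follow Beta(1,3)", {
  g <- simulate_genotypes(500, 200, seed = 11)
  expect_equal(dim(g$genotypes), c(500, 200))
  expect_lt(max(abs(colMeans(g$genotypes))), 1e-12)
  expect_lt(max(abs(apply(g$genotypes, 2, var) - 1)), 1e-12)
  expect_true(all(g$mafs >= 0.01 & g$mafs <= 0.5))

  # Monte-Carlo oracle for the truncated Beta(1,3) mean, independent draw
  set.seed(4242)
  b <- rbeta(2e5, 1, 3)
  oracle_mean <- mean(b[b >= 0.01 & b <= 0.5])
  g2 <- simulate_genotypes(50, 5000, seed = 12)
  expect_equal(mean(g2$mafs), oracle_mean, tolerance = 0.02)
})

test_that("degenerate genotype draws are redrawn, never monomorphic", {
  # tiny n with low-MAF variants makes all-zero columns likely
  g <- simulate_genotypes(4, 300, seed = 5)
  expect_true(all(is.finite(g$genotypes)))
  expect_lt(max(abs(apply(g$genotypes, 2, var) - 1)), 1e-12)
  expect_error(simulate_genotypes(1, 5), "n")
  expect_error(simulate_genotypes(10, 0), "m")
})

test_that("effect sizes are rescaled to the target heritability exactly", {
  for (h2 in c(0.2, 0.5, 0.8)) {
    b <- draw_effect_sizes(runif(50, 0.05, 0.5), h2, seed = 3)
    expect_equal(sum(b^2), h2, tolerance = 1e-12)
  }
  expect_equal(abs(draw_effect_sizes(0.3, 0.5, seed = 1)), sqrt(0.5))
  expect_error(draw_effect_sizes(numeric(0), 0.5), "non-empty")
  expect_error(draw_effect_sizes(c(0.1, 0.7), 0.5), "0.5")
})

test_that("effect-size variance scales with (p(1-p))^-0.25 across MAF groups", {
  m <- 5000
  b <- draw_effect_sizes(c(rep(0.1, m), rep(0.4, m)), 0.5, seed = 21)
  ratio <- var(b[1:m]) / var(b[(m + 1):(2 * m)])
  expect_equal(ratio, (0.1 * 0.9)^-0.25 / (0.4 * 0.6)^-0.25,
               tolerance = 0.08)
})

test_that("causal function families evaluate correctly", {
  expect_equal(
    evaluate_causal_function(causal_fun("polynomial", c(0, 0.1, 0.05)), 1),
    0.15)
  expect_equal(
    evaluate_causal_function(causal_fun("sigmoid", scale = 0.1,
                                        steepness = 2), 0), 0.05)
  expect_equal(
    evaluate_causal_function(causal_fun("signed_sqrt", scale = 0.1), -4),
    -0.2)
  expect_equal(
    evaluate_causal_function(causal_fun("exponential", scale = 0.1), 0),
    0.1)
  # Horner evaluation matches direct powers on a cubic
  f <- causal_fun("polynomial", c(0.3, -0.2, 0.1, 0.05))
  x <- seq(-3, 3, by = 0.5)
  expect_equal(evaluate_causal_function(f, x),
               0.3 - 0.2 * x + 0.1 * x^2 + 0.05 * x^3)
  expect_error(causal_fun("polynomial"), "coefficients")
})

test_that("simulated datasets satisfy their construction identities", {
  st <- small_settings(n = 5000, m = 30, seed = 9)
  d <- simulate_dataset(st)
  expect_equal(sum(d$true_beta^2), 0.5, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(d$genotypes))), 1e-10)
  # exposure identity X = G beta + q_x U + eps_x
  recon <- as.vector(d$genotypes %*% d$true_beta) +
    st$q_x * d$confounder + d$exposure_noise
  expect_equal(d$exposure, recon, tolerance = 1e-12)
  # unit-variance construction for both traits
  expect_equal(var(d$exposure_std), 1, tolerance = 1e-12)
  expect_equal(var(d$outcome), 1, tolerance = 1e-12)
  expect_equal(var(d$outcome_raw), 1, tolerance = 0.1)
  # genetic component orthogonal-ish to exposure noise
  expect_lt(abs(cor(as.vector(d$genotypes %*% d$true_beta),
                    d$exposure_noise)), 0.05)
})

test_that("same seed regenerates a bitwise-identical dataset", {
  st <- small_settings(n = 300, m = 10, seed = 77)
  expect_identical(simulate_dataset(st), simulate_dataset(st))
  st2 <- st; st2$seed <- 78L
  expect_false(identical(simulate_dataset(st)$outcome,
                         simulate_dataset(st2)$outcome))
})

test_that("null causal effect without confounding decorrelates X and Y", {
  st <- polymr_settings(n_samples = 20000, n_causal_snps = 10, q_x = 0,
                        q_y = 0, q_y2 = 0,
                        causal_function = causal_fun("polynomial", 0),
                        seed = 31)
  d <- simulate_dataset(st)
  expect_lt(abs(cor(d$exposure, d$outcome)), 0.02)
})

test_that("p values of corr(X, Y) are uniform under the global null", {
  st <- polymr_settings(n_samples = 200, n_causal_snps = 5, q_x = 0,
                        q_y = 0, q_y2 = 0,
                        causal_function = causal_fun("polynomial", 0),
                        seed = 1)
  pv <- vapply(seq_len(1000), function(i) {
    st$seed <- 5000L + i
    d <- simulate_dataset(st)
    cor.test(d$exposure, d$outcome)$p.value
  }, numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("exposure variance concentrates at 1 across replicates", {
  st <- polymr_settings(n_samples = 1e5, n_causal_snps = 100, seed = 1)
  vx <- vapply(seq_len(25), function(i) {
    st$seed <- 900L + i
    var(simulate_dataset(st)$exposure)
  }, numeric(1))
  expect_true(all(vx > 0.98 & vx < 1.02))
})

test_that("instrument selection retains strong variants and drops null ones", {
  set.seed(61)
  n <- 20000
  g_null <- rnorm(n)
  g_strong <- rnorm(n)
  x <- 0.1 * g_strong + rnorm(n, sd = sqrt(0.99))
  ivs <- select_instruments(cbind(g_null, g_strong), x, 5e-8)
  expect_identical(ivs, 2L)
  # order preserved, empty result allowed
  expect_length(select_instruments(cbind(rnorm(500)), rnorm(500), 5e-8), 0)
  expect_error(select_instruments(cbind(g_null), x[1:10], 5e-8), "length")
})

test_that("settings validation rejects impossible parameters", {
  expect_error(polymr_settings(heritability = 0.9, q_x = 0.5), "q_x")
  expect_error(polymr_settings(heritability = 1.2), "heritability")
  expect_error(polymr_settings(n_samples = 1), "n_samples")
  expect_error(polymr_settings(n_causal_snps = 0), "n_causal_snps")
})
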