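---
title: "Polynomial Mendelian randomization: model, estimation and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polynomial Mendelian randomization: model, estimation and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymr)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure $X$ (say, BMI) on an
outcome $Y$ (say, LDL cholesterol) from observational data, exploiting the
random allocation of alleles at conception. Almost all MR methods assume
this effect is *linear*. Many real exposure-outcome relationships are not:
effects can attenuate at the extremes, plateau, or reverse direction. This
package estimates a polynomial approximation of an arbitrary causal
function from individual-level genotype data, together with pointwise
confidence hulls, a formal test of non-linearity, and the causally
explained variance.

## Model

Both traits are standardized to zero mean and unit variance, so all
coefficients are in SD units. With genotype matrix $G$ (standardized
dosages of the instruments) the structural model is

$$X = G\beta + \epsilon_x, \qquad Y = \sum_{j=0}^{k} \alpha_j X^j + \epsilon_y.$$

Confounding and reverse causation make $\epsilon_y$ and $\epsilon_x$
correlated. Decomposing $\epsilon_y$ into a polynomial in $\epsilon_x$ plus
independent noise $\tau_y$ gives the estimating equation

$$Y = \sum_{j=0}^{k} \alpha_j X^j + \sum_{j=1}^{l} r_j (X - G\beta)^j + \tau_y,$$

whose error is uncorrelated with every regressor. Estimation is therefore
two ordinary least-squares stages: regress $x$ on all instruments jointly
to obtain $\hat\beta$ and the control-function variable
$e = x - G\hat\beta$, then regress $y$ on
$[1, x, \ldots, x^k, e, \ldots, e^l]$. With $k = l = 1$ this is exactly the
textbook control-function estimator, and the coefficient on $x$ equals the
two-stage least-squares slope (a property the test suite checks to 1e-8).
The exposure powers $\alpha_j$ carry the causal signal; the
control-function powers $r_j$ absorb confounding of matching order, which
is why a first-order control function (`polymr_l1()`) is biased by
quadratic confounding while the full model is not.

The key identifying assumptions are the classical MR ones (relevance,
exchangeability, exclusion restriction) plus effect-strength independence
so that $\mathrm{cov}(G\beta, \epsilon_y) = 0$. Estimation error in
$\hat\beta$ is ignored in second-stage inference; the resulting bias is
small at biobank sample sizes and a maximum-likelihood correction is out of
scope.

## Key parameters

* `k`, `l` (default 10 and 10): highest exposure and control-function
  powers. Ten gives the causal curve ample flexibility while keeping the
  design manageable; `l = 1` reproduces the standard control-function
  baseline.
* `alpha_level` (default 0.05): backward elimination keeps an exposure
  coefficient of order $\ge 2$ only if its two-sided OLS p value is below
  `alpha_level / k` — a Bonferroni correction over the `k` candidate
  powers, fixed at the initial `k` (0.005 by default) throughout the
  elimination path.
* `reverse_filter` (default on): instruments whose standardized marginal
  effect is larger in absolute value on the outcome than on the exposure
  are more plausibly acting through the outcome and are removed; equality
  retains the instrument.
* `n_draws` (default 10,000 for reporting; 1,000 in the test suite): the
  95% confidence hull is formed by drawing coefficient vectors from their
  estimated multivariate normal distribution, anchoring every drawn curve
  at the mean exposure, and taking pointwise 2.5/97.5 percentiles.

### Backward selection: which coefficient to drop

The elimination rule removes, at each refit, the *highest-order*
non-significant exposure coefficient (the intercept and the linear term
are never candidates), then truncates the control-function powers to the
highest surviving exposure order. We also implemented the alternative of
removing the *least significant* coefficient first and measured both on
the weak-quadratic scenario: because high even powers of a near-Gaussian
exposure are strongly collinear with $x^2$, the least-significant-first
rule frequently discards the true quadratic and retains a spurious
high-order term instead (exact-order-2 detection drops from roughly 0.86
to 0.38). Highest-order-first respects the marginality principle for
polynomial models — high-order terms are dropped before the low-order
terms they dominate — and is the package default.

### Non-linearity test and causally explained variance

After selection, the non-linearity p value comes from a likelihood-ratio
test of the final model against the model with exposure powers restricted
to the linear term, with the retained control-function columns frozen;
the statistic is $n \log(\mathrm{RSS}_\mathrm{lin}/\mathrm{RSS}_\mathrm{full})$
(Gaussian likelihood with the error variance profiled out) on as many
degrees of freedom as retained exposure orders $\ge 2$, with $p = 1$ by
convention when none is retained. The causally explained variance is the
$r^2$ difference between the final model and the model retaining only the
control-function columns. Note a subtlety: because $e$ is correlated with
$x$ (share $1 - h^2$ of its variance), the control-function-only model
already explains part of the genuinely causal variance, so this quantity
is a conservative lower summary of the causal contribution — for a
noiseless quadratic with $h^2 = 0.5$ it is about 0.55, not 1.

## The simulator

`simulate_dataset()` generates the confounded data-generating process used
throughout the simulation study:

* MAFs $p_i \sim \mathrm{Beta}(1, 3)$, redrawn until inside
  $[0.01, 0.5]$ (keeps "minor"-allele semantics and rules out
  near-monomorphic variants; the bounds are a package choice);
* dosages $\sim \mathrm{Binomial}(2, p_i)$, each column standardized;
* effects $\beta_i \sim N(0, (p_i(1-p_i))^{-0.25})$ — rarer variants get
  larger standardized effects, as under selection-aware heritability
  models — rescaled so $\sum \beta_i^2 = h^2$ exactly;
* a shared confounder $U \sim N(0,1)$ entering the exposure as $q_x U$ and
  the outcome as $q_y U + q_{y2} U^2$;
* exposure noise variance $1 - h^2 - q_x^2$, so $\mathrm{Var}(X) = 1$ in
  expectation, with the exposure empirically re-standardized before the
  causal function is applied;
* outcome noise variance set to the complement of the realized signal
  variance (causal + confounder terms), so $\mathrm{Var}(Y) = 1$ by
  construction, then empirical standardization. This unit-variance
  convention is what makes the strong-confounding scenario
  ($q_x = 0.5$, $q_y = 0.8$, null causal effect) produce a trait
  correlation of exactly $q_x q_y = 0.4$, and what lets the estimator
  recover the generative coefficients on their stated scale. (Drawing
  $\epsilon_y \sim N(0,1)$ instead would inflate $\mathrm{Var}(Y)$ to
  about 1.27 under the base settings and attenuate every recovered
  coefficient by that standard deviation.)

The base scenario uses $n = 100{,}000$ individuals, $m = 100$ causal
variants, $h^2 = 0.5$, moderate confounding ($q_x = 0.2$, $q_y = 0.5$,
$q_{y2} = 0$) and the quadratic causal function $0.1X + 0.05X^2$;
`polymr_scenarios()` ships all causal-function shapes (null, linear,
stronger, weak quadratic, cubic, fourth-order, mixed, exponential, signed
square root, three sigmoids) and the confounding variations. Instruments
are the causal variants that reach marginal genome-wide significance
($p < 5 \times 10^{-8}$) in the simulated sample itself — a deliberate
mirror of single-sample MR practice, winner's curse included.

What the simulator does *not* emulate: linkage disequilibrium between
variants, pleiotropic instruments (violations of effect-strength
independence), population structure, binary traits, and assortative
mating. Passing tests therefore demonstrate correctness of the estimator
under the stated generative model, not robustness to these real-data
complications.

## The replicate harness

`run_replicates()` repeats simulate / select instruments / fit, evaluates
every fitted curve on the 1-99 percentile grid of the true (standard
normal) exposure distribution, anchored at the mean exposure, and
aggregates per-percentile mean bias, RMSE, predicted versus empirical 95%
interval widths, truth coverage, the distribution of the highest retained
exposure order, and mean coefficients with eliminated coefficients counted
as zero. Per-replicate seeds derive deterministically from the master
seed, so results are reproducible and order-independent; replicates whose
instrument selection comes back empty are skipped, warned about, and
counted, with metrics computed over completed replicates.

## Numerical choices

* Exposure, outcome, and genotype columns are standardized before any
  powers are formed.
* The backward-selection path runs on a cached cross-product of the
  centered and per-column-scaled power basis (selection decisions are
  invariant to that rescaling, and each step becomes $O(p^3)$); the final
  reported model is refit by QR decomposition.
* The first stage uses a Cholesky solve of the instrument Gram system when
  it is well-conditioned (condition number below $10^4$; the norm for
  LD-pruned instruments) and falls back to a rank-revealing QR otherwise.
* A condition-number warning fires when the column-normalized second-stage
  design exceeds $10^8$.
* Non-positive-semidefinite coefficient covariances (possible only through
  external manipulation or extreme degeneracy) are eigenvalue-clipped at
  zero before hull draws, with a warning.
* Rows with missing values are dropped as complete cases, with a logged
  count. Constant exposures, rank-deficient instrument sets and
  insufficient samples raise immediate, named errors.

## Problem sizes used by the shipped checks

The replicate studies in the acceptance checks run the full study
conditions ($n = 100{,}000$, $m = 100$) at 200 replicates. The
distributional property suites use reduced sizes chosen to keep each
property well-powered: LRT calibration at $n = 5{,}000$ over 1,000
replicates; hull calibration at $n = 10{,}000$ over 150 replicates;
control-function comparisons at $n = 20{,}000$ over 30 replicates; RMSE
monotonicity at $n \in \{5{,}000, 50{,}000\}$ over 40 replicates.

## Known limitations

* The weak-quadratic scenario ($\alpha_2 = 0.01$) has an exact-order-2
  detection rate of about 0.81-0.86 under this implementation. That is the
  mathematical ceiling at these settings: the quadratic $t$ statistic in
  the final candidate model has mean 3.93 (matching its analytic value)
  and unit spread, so at the fixed 0.005 threshold no elimination path can
  detect more often. Higher detection rates for this scenario are
  achievable only by relaxing the threshold along the elimination path
  (e.g. re-dividing by the current number of candidates) or by excluding
  the quadratic control-function column while testing the quadratic
  exposure term; both conflict with the procedure as documented here, so
  we keep the stricter rule.
* With backward selection active, the non-linearity test is conservative
  under a linear truth (empirical type-I error ~2% at nominal 5%),
  because rejection first requires a coefficient to survive the Bonferroni
  screen. The unselected (`select = FALSE`) test is calibrated.
* First-stage estimation error is ignored; instruments are selected and
  fit in the same sample (winner's curse), as in single-sample MR
  practice.
* Curve estimates beyond the 1st-99th exposure percentiles are
  extrapolations of a polynomial and should not be interpreted.

## A worked example

```{r example, eval = FALSE}
st <- polymr_scenarios("base", seed = 42)
d <- simulate_dataset(st)
ivs <- select_instruments(d)          # genome-wide significant variants
fit <- polymr(d$exposure, d$outcome, d$genotypes[, ivs])
summary(fit)
plot(fit, n_draws = 1000, seed = 1)
```
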