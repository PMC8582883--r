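---
title: "Mixed logit severity models with heterogeneity in means and variances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed logit severity models with heterogeneity in means and variances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmvlogit)
library(dplyr)
```

## The model

Crash injury severity is recorded on a four-level scale — no injury, minor,
severe, fatal — and modelled as an unordered discrete outcome. Each level
$i$ of crash $k$ has a linear severity function

$$F_{ik} = \beta_{ik} X_{ik} + \varepsilon_{ik},$$

with i.i.d. extreme-value disturbances, so conditional on the coefficients
the outcome probabilities are multinomial logit. The baseline level
(no injury, the modal category) has its severity function constrained to
zero; the three remaining levels carry alternative-specific constants.

What distinguishes the random-parameters (mixed) logit used here is that a
coefficient may vary across crashes. A random coefficient is normal with a
crash-specific mean and standard deviation,

$$\beta_{ik} = \beta + \theta' Z_{ik} + \sigma \exp(\omega' W_{ik})\,
\gamma_{ik}, \qquad \gamma_{ik} \sim N(0, 1),$$

where $Z$ ("mean links") shifts the coefficient's mean, $W$ ("variance
links") scales its standard deviation multiplicatively, and $\theta$,
$\omega$ are estimated link parameters. With all links empty this is the
ordinary mixed logit; with $\sigma = 0$ it collapses to the multinomial
logit. Only the normal mixing distribution is supported: it is the form
that survives distributional screening in this literature, and supporting a
single form keeps the simulated kernel and its gradients exact.

The unconditional choice probability integrates the logit kernel over the
mixing distribution. That integral has no closed form, so it is simulated:
for each crash the kernel is averaged over $R$ standard-normal draws, and
the sum of log average probabilities is maximized (maximum simulated
likelihood).

## Halton draws

The simulation nodes are Halton sequences — prime-base radical-inverse
points transformed through $\Phi^{-1}$ — rather than pseudo-random draws.
They cover (0, 1) far more evenly, which cuts the simulation noise of the
probability average at a given $R$; the test suite verifies their
Kolmogorov–Smirnov distance to $N(0,1)$ beats an average pseudo-random
sample of the same size. Conventions the package fixes (and documents here
because no standard exists):

* **R = 200 draws per crash** by default, a conventional operating point
  for Halton-based estimation of models of this size. Configurable via
  `n_draws`.
* **burn = 10**: the first ten points of each sequence are discarded,
  removing the degenerate early run of small fractions.
* **One prime per random slot**, in order (2, 3, 5, ...), extended on
  demand.
* **Consecutive partition**: crash $k$ receives stream points
  $(k-1)R + 1, \dots, kR$. Interleaving would be equally valid; fixing one
  convention makes every run bit-reproducible.
* No scrambling or shifting; draws are never serialized because they are
  cheap to regenerate deterministically.

Because the draw block depends only on $(n, R, \text{burn})$, every
likelihood evaluation during optimization sees the same draws ("common
draws"), keeping the simulated objective smooth, and identical settings
reproduce log-likelihoods exactly.

## Estimation

`ml_fit()` maximizes the simulated log-likelihood with BFGS. The gradient
is analytic — the standard simulated-likelihood score, assembled per draw
from the logit residuals — and is verified against central differences in
the tests. Analytic scores also give each observation's contribution, used
for the BHHH fallback below. When the specification contains random slots,
starting values come from a fixed-coefficient pre-fit of the same
structure: random-slot means start at the MNL estimates, standard
deviations at 0.1, links at zero. This warm start roughly halves the
iteration count and keeps the optimizer out of the flat regions that a
cold start in a high-dimensional simulated likelihood can wander into.

Standard errors are taken from the inverse of the negative numerical
Hessian (central differences of the analytic gradient, symmetrized) at the
optimum. If that matrix fails a Cholesky factorization, the BHHH outer
product of scores is used and the fit records `vcov_method = "bhhh"`; if
that too is singular, standard errors are reported as undefined rather
than invented. $\sigma$ is estimated unconstrained — its sign is not
identified under a symmetric mixing distribution — and reported as
$|\sigma|$.

Numerical safeguards: utilities are max-stabilized per draw before
exponentiation, so overflowing candidate parameters give valid
probabilities instead of NaN; averaged probabilities are floored at the
smallest positive normal double before the log; non-finite candidate
vectors return a large penalty to the optimizer.

The `retention_screen()` implements the conventional specification screen:
a parameter is retained when its two-tailed $t$-statistic reaches the 90%
confidence level ($|t| \ge 1.645$); random-slot standard deviations are
screened the same way. The screen flags, it does not drop — specification
choices remain with the analyst.

## The model ladder and likelihood-ratio tests

`nested_ladder()` builds the three specifications usually reported side by
side: no mean–variance heterogeneity (all links removed), heterogeneity in
means only ($W$ removed), and the full model. `fit_ladder()` estimates
them sequentially with warm starts, so the log-likelihood at convergence
is non-decreasing along the ladder (a property the tests assert), and
`lr_nested()` compares adjacent rungs.

Two cross-dataset tests support the decision to model data subsets (e.g.
peak vs off-peak periods) separately:

* **Separation:** with the same variable set fitted to the pooled data and
  each subset, $\mathrm{LR} = -2[LL_{pool} - LL_a - LL_b]$ is chi-square
  with $K_a + K_b - K_{pool}$ degrees of freedom.
* **Transferability:** $\mathrm{LR} = -2[LL(\beta_{ab}) - LL(\beta_b)]$,
  where $LL(\beta_{ab})$ evaluates subset $a$'s converged parameters on
  subset $b$'s data. The literature's verbal description of
  $\beta_{ab}$ is ambiguous between "held fixed" and "re-estimated"; the
  package implements the standard fixed-parameter version
  (`transfer_loglik()`), under which the statistic is non-negative by
  construction and the degrees of freedom equal the number of estimated
  parameters.

Negative statistics beyond a $10^{-4}$ optimizer tolerance raise an error
pointing at non-convergence instead of being clamped silently.

Goodness of fit follows the standard formulas: McFadden
$\rho^2 = 1 - LL/LL_0$, adjusted $\rho^2 = 1 - (LL - K)/LL_0$,
$\mathrm{AIC} = 2K - 2LL$, $\mathrm{BIC} = K\ln n - 2LL$, with $LL_0$ the
constants-only log-likelihood (available in closed form as
$\sum_i n_i \ln(n_i/n)$). Published severity studies occasionally print
fit tables whose $\rho^2$/AIC/BIC are mutually inconsistent with their
log-likelihoods; this package always derives the metrics from the fitted
log-likelihood.

## Post-estimation reporting

**Marginal effects** for a binary indicator are average discrete changes:
toggle the covariate to 1 and to 0 for every crash (including wherever it
appears in $Z$ or $W$ links), average the simulated probabilities over the
estimation sample in both scenarios, and difference. Because both
scenarios' probabilities sum to one, each covariate's effects sum to zero
across the four levels — an invariant the tests check to float precision.
The averaging convention (whole estimation sample, converged point
estimates, no delta-method standard errors) is stated here because
published tables rarely say which convention they use.

**Random-parameter summaries** (`random_param_summary()`) report, at a
chosen setting of the link covariates: the conditional mean
$\mu_c = \beta + \theta'Z$, the conditional SD
$\sigma_c = |\sigma|e^{\omega'W}$, and the share of the population with a
negative coefficient, $\Phi(-\mu_c/\sigma_c)$. Two variance figures are
emitted side by side:

* `conditional_variance` $= \sigma_c^2$ — the model's actual conditional
  variance, consistent with the likelihood;
* `additive_variance` $= \sigma^2 + \omega'W$ — an additive convention
  seen in applied severity reports. It is **not** the model's variance and
  is labelled as a reporting convention; it is provided so results can be
  compared against tables that use it.

Note that published "share below zero" figures do not always equal
$\Phi(-\mu/\sigma)$ for the printed $(\mu, \sigma)$ pair; this package
always reports the $\Phi$ value implied by its own estimates.

`density_curve()` and the `autoplot()` methods draw the conditional normal
densities on a $\mu_c \pm 4\sigma_c$ grid (trapezoid mass within $10^{-3}$
of one), a degenerate $\sigma_c = 0$ slot being returned as a point mass.

## The synthetic-data generator

Because crash registries are typically access-restricted,
`simulate_crashes()` generates datasets with the statistical structure the
analysis assumes and attaches a ground-truth manifest (configuration,
realized normal deviates, per-crash choice probabilities):

* covariates are independent Bernoulli indicators; the default
  `crash_covariate_profile()` uses occurrence rates typical of urban
  automobile–e-bike crash registries (91% male drivers would appear here
  as its complement for the female-rider indicator, 79% road segments,
  20% low visibility, and so on);
* each crash receives one pseudo-random normal deviate per random slot —
  deliberately *not* Halton, so generation and estimation draws are
  independent by construction;
* coefficients are realized by the same mean/variance construction as the
  likelihood, and the outcome is sampled from the four-category logit
  probabilities.

The default `default_crash_spec()`/`default_true_params()` pair mirrors
the structure of a fitted mean–variance heterogeneity model (two random
visibility coefficients on the severe-injury function, mean and variance
links on traffic control and night lighting). It is illustrative — a
realistic operating point, not ground truth about any city.

What the generator does **not** emulate — and hence what passing recovery
tests do and do not show — matters: real crash indicators are correlated
(the generator draws them independently), registries contain missingness
and miscoding (the reader rejects rather than imputes), and real
heterogeneity need not be exactly normal. Recovery of generating
parameters demonstrates the estimator is correct under its own
assumptions, not that those assumptions hold in any particular registry.

## Calibration experiments and problem sizes

The test suite runs each verification at a size chosen to balance
statistical resolution against runtime; these are the package's chosen
operating points:

* **Parameter recovery:** one random slot with one mean and one variance
  link, $n = 5000$, $R = 200$, five seeded replicates; each true parameter
  should land within three reported standard errors in at least 90% of
  checks (observed: 96%).
* **Quadrature cross-check:** simulated probabilities at $R = 200$ against
  a 64-node Gauss–Hermite reference, agreement within 0.005.
* **Separation-test calibration:** two periods of $n = 500$ drawn from a
  shared fixed-coefficient process (8 parameters), 50 replicates; the mean
  statistic should sit within 15% of its chi-square degrees of freedom.
  For the power arm, a +1.0 shift is placed on the *road-segment*
  coefficient — a 70%-prevalence covariate — because a shift of that size
  on a rare covariate (25% prevalence) is simply not identifiable at
  $n = 500$ per side (~40% power in a pre-test power analysis, versus
  ~100% on the common covariate). The calibration's premise is a
  detectable regime difference, so the shift is placed where the design
  can detect it; detecting shifts on rare covariates requires the larger
  samples a real registry analysis would use.

## Degenerate inputs and tie-breaks

* A severity category absent from the data contributes $0 \cdot \ln 0 = 0$
  to the constants-only log-likelihood; a missing *baseline* category
  makes constants inestimable and `ml_fit()` refuses with an explanation.
* Covariate probabilities of exactly 0 or 1 in the generator produce
  constant columns (valid, though such a covariate's coefficient is then
  unidentified alongside the constant).
* Duplicate (covariate, severity) slots, random slots on the baseline, and
  link covariates absent from the data are configuration errors, raised at
  specification time, not fit time.
* Parameter order — constants, fixed slots, random means, SDs, mean links,
  variance links — is total and stable, so warm starts and serialized
  reports never depend on hash order.

## Known limitations

* No correlated random parameters (no Cholesky cross-terms) and no panel
  structure: each crash is one observation.
* Only binary indicator covariates; continuous covariates would need
  centring conventions the severity literature does not standardize.
* No delta-method standard errors for marginal effects.
* Uniform and triangular mixing distributions are not implemented.
* The covariate-correlation hook in the generator defaults off; all
  defaults generate independent indicators.
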