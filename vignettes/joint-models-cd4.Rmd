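---
title: "Joint models for CD4 count and mortality: association structures, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint models for CD4 count and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jmassoc)
```

## The modelling problem

In HIV/TB cohorts the CD4 count is measured repeatedly while patients are at
risk of death. CD4 is an *endogenous* time-varying covariate: its path is
generated by the patient and is interrupted by death, so feeding raw
measurements into a Cox model with last-observation-carried-forward (LOCF)
imputation is known to bias the association towards zero (measurement error
and the step-function approximation both attenuate). A shared-random-effects
joint model addresses this by modelling the *true* trajectory and the hazard
together.

`jmassoc` implements the complete analysis: the longitudinal sub-model, a
relative-risk survival sub-model under four association structures,
Bayesian estimation by MCMC, DIC/LPML structure selection, classical
survival descriptives, the LOCF time-varying Cox comparator, and a
synthetic trial generator so that the whole pipeline runs without any
restricted data.

## The two sub-models

**Longitudinal.** Square-root CD4 (the square root normalises the
characteristically right-skewed counts) follows a natural-cubic-spline
mixed model

$$y_i(t) = (\beta_0 + b_{i0}) + (\beta_1 + b_{i1}) B_1(t) +
  (\beta_2 + b_{i2}) B_2(t) + \varepsilon_i(t),$$

with one interior knot at the median of the pooled measurement times,
$b_i \sim N(0, D)$ unstructured and
$\varepsilon_i(t) \sim N(0, \sigma^2_\varepsilon)$ i.i.d. The noise-free
part $m_i(t)$ is the "true" trajectory. Time is in months throughout;
person-years appear only in the rate reports.

**Survival.** A relative-risk model

$$h_i(t) = h_0(t) \exp\{\gamma_1 \text{Arm}_i + \gamma_2 \text{Age}_i +
  \gamma_3 \text{Gender}_i + f(m_i(\cdot); \alpha)\},$$

with $\log h_0(t)$ an intercept plus a cubic B-spline expansion over
follow-up. The association functional $f$ is one of

* **current value**: $\alpha\, m_i(t)$;
* **time-dependent slopes**: $\alpha_1 m_i(t) + \alpha_2 m_i'(t)$;
* **cumulative (area)**: $\alpha \int_0^t m_i(s)\,ds$;
* **weighted cumulative**: $\alpha \int_0^t \varpi(t-s)\, m_i(s)\,ds$ with
  a normal kernel $\varpi$ normalised to integrate to one over
  $[0, t_{\max}]$, $t_{\max}$ the maximum follow-up time of the dataset.
  The kernel scale $\sigma_w$ is a parameter, estimated from the data on
  the log scale.

A deliberate reading of the weighted form: the kernel's normaliser
integrates over $[0, t_{\max}]$ regardless of the current $t$, so the
weights at an early time $t$ need *not* sum to one over $[0, t]$. Parts of
the weighted-cumulative-exposure literature normalise over $[0, t]$
instead; the fixed-normaliser version keeps $\alpha$ comparable across
event times and makes the $\sigma_w \to \infty$ limit the plain area scaled
by $1/t_{\max}$.

All covariates are baseline values; lagged, interaction and
random-effects-only association structures are out of scope, as are
competing risks and left truncation.

## Spline machinery

The trajectory basis is built from cubic B-splines with the natural
constraints (zero second derivative at both boundary knots) imposed by a
null-space projection, plus a zero-value constraint at the lower boundary
so the constant function is left to the model intercept. The *column space*
is the contract — tests compare fitted functions against an independent
truncated-power construction, not coefficients. Beyond the boundary knots
every basis function continues along its tangent line; this matters because
death times routinely exceed the last CD4 measurement time, and the
trajectory model must extrapolate linearly there rather than error out.

Derivatives are analytic; integrals are computed piecewise with a 5-point
Gauss–Legendre rule per polynomial piece, which is exact for cubics.

The baseline-hazard spline defaults to degree 3 with five interior knots at
equally spaced percentiles of the observed event times. Because the full
B-spline basis sums to one, the explicit intercept $k_0$ would be aliased;
the first basis column is dropped, giving $k_0$ plus $Q + g$ free
coefficients.

## Numerical integration

* `cumulative_hazard()` uses 15-point Gauss–Legendre on $[0, T]$, split
  into 7 equal panels when $T > 12$ months.
* `m_weighted_area()` integrates in elapsed time $u = t - s$. When the
  kernel is concentrated ($\sigma_w < t/10$) the panels are graded towards
  $u = 0$ with edges at $\{0, 3, 10, 30, 100\}\,\sigma_w$; a fixed uniform
  subdivision cannot resolve kernels much narrower than a panel, and the
  graded layout keeps the rule accurate down to $\sigma_w \approx 10^{-3}
  t_{\max}$ (verified against $10^5$-point trapezoid oracles).
* Inside the sampler the weighted structure uses a fixed graded inner rule
  (panel edges at 0, 1, 4, 12 months and the node time, 7 points per
  panel): $\sigma_w$ changes during sampling, so the node layout must not
  depend on it; grading towards $u = 0$ covers every scale the posterior
  visits. The factorisation of the weighted integrand into a
  coefficient-dependent part and a kernel-dependent part is exploited so
  that updates of $(\gamma, \alpha, k)$ reuse the association functional
  and updates of $\sigma_w$ reuse the trajectory evaluations.

## Estimation

The posterior is sampled by adaptive Metropolis-within-Gibbs with three
ingredients that matter for mixing at trial scale:

* **Covariance-adapted blocks** for $\beta$, $(\gamma, \alpha)$, $k$ and
  the random-effect correlations: each block's proposal is a scalar step
  size (Robbins–Monro-tuned towards 0.234) times a Cholesky preconditioner
  learned from the chain's own running covariance during adaptation and
  frozen afterwards. The baseline-spline coefficients are strongly
  correlated, and an isotropic walk on them is the single worst mixing
  bottleneck otherwise.
* **Conjugate independence proposals for the random effects**: all $b_i$
  are proposed in parallel from their exact Gaussian conditional given the
  longitudinal data (and current $\beta$, $\sigma^2_\varepsilon$, $D$); the
  Gaussian factors cancel in the Metropolis–Hastings ratio, which reduces
  to the survival-likelihood ratio, so acceptance sits near 1 and the
  latent effects decorrelate almost instantly. When the survival part is
  switched off this is an exact Gibbs step.
* **A centering sweep**: the translation $(\beta + \delta,\, b_i - \delta)$
  leaves both likelihoods unchanged (only $\beta + b_i$ enters them), and
  $\delta$ has a Gaussian full conditional from the random-effects density
  and the $\beta$ prior. Without this Gibbs move the sampler crawls along
  the $\beta$-versus-mean($b$) ridge.

$\sigma^2_\varepsilon$ is conjugate Gibbs; the random-effect scales and
$\log \sigma_w$ use scalar log-walks tuned towards 0.44. The $\sigma_w$
update runs every fourth sweep: each move re-aggregates the inner
quadrature over all nodes, and the kernel scale is the most weakly
identified parameter in the model.

Priors (the package's choice, recorded in the fit object): coefficients
$N(0, 100)$; $\sigma^2_\varepsilon \sim$ Inverse-Gamma(0.01, 0.01); $D$
decomposed into Half-Cauchy(2.5) scales and a uniform correlation matrix;
$\log \sigma_w \sim N(\log(t_{\max}/4), 1)$. Defaults are 3 chains, 1,000
adaptation, 1,000 burn-in and 2,000 kept iterations. Initial values come
from cheap classical fits: pooled and per-subject least squares for the
trajectory side, a Poisson-offset exponential fit for $\gamma$, a
piecewise-constant hazard projection for $k$, and $\alpha = 0$.

Two estimation modes exist purely for validation: `likelihood =
"longitudinal"` drops the survival term (used with fixed random effects to
compare against the closed-form Gaussian conjugate posterior of $\beta$)
and `likelihood = "none"` samples the prior through the same kernel (a
sampler-correctness check; prior moments must be recovered).

## Model comparison

The deviance is $-2$ times the conditional-on-$b_i$ data log-likelihood
(longitudinal + survival, full constants, additive constant fixed at zero).
$p_D$ is the mean posterior deviance minus the deviance at the
componentwise posterior mean with the random effects included in the mean —
the conditional-DIC convention standard for hierarchical joint models; the
marginal alternative would require integrating over $b_i$ per draw and the
conditional one matches how these models are compared in practice. LPML is
the sum of log conditional predictive ordinates, each the harmonic mean of
the subject's per-draw conditional likelihood, computed with a max-shift in
log space. Structures are ranked by ascending DIC; exact ties are broken by
the order the fits were supplied.

## The synthetic trial generator

`simulate_trial()` draws complete trials from the exact generative model.
The default design emulates the kind of three-point ART-timing trial the
package targets: 642 subjects, 2:1 allocation to the combined integrated
arms, age $\sim N(34.2, 8.3^2)$ truncated at 18 years, 49.7% male,
administrative censoring at 60 months. The CD4 visit schedule (0, 2, 6, 12,
18, 24 months) and the exponential dropout rate (0.035/month) are plausible
stand-ins — the real cadence and censoring pattern of such trials are not
part of the public record — and both are configurable. Defaults that are
calibration targets rather than free choices: baseline sqrt-CD4 near 12
(median CD4 ≈ 145 cells/mm³), recovery towards 16 by 24 months, arm and
gender hazard ratios near 0.6, and per-structure baseline offsets fixed
once so that the marginal death fraction lands near 10.7% with most deaths
in the first year (the generator's declining baseline hazard produces the
early-death concentration).

Event times are drawn by inverse-CDF sampling: $U \sim \text{Unif}(0,1)$
and $H_i(T) = -\log U$ solved by bracketed root finding on a dense
tabulation of the subject's cumulative hazard (1,201 grid points over the
censoring horizon; trapezoid increments, linear inversion inside the
bracketing cell). The tabulation error is far below the Kolmogorov–Smirnov
tolerance used to validate the generator against the independently
quadrature-integrated survival function.

What the generator does *not* emulate: informative dropout, visit-time
irregularity, arm effects on the CD4 trajectory (available as an explicit
misspecification stressor via `arm_effect_on_trajectory = TRUE`, since the
fitted longitudinal model carries no covariates), interval censoring, or
TB-treatment covariates. Passing tests therefore demonstrate correctness of
the machinery under the model's own assumptions, not robustness to the ways
real trial data violate them.

## Scale of the shipped experiments

The simulation experiments in the test suite are smoke-scale versions of
their full-size designs; the package chose these sizes to keep a complete
check run at desk scale:

* parameter recovery: 5 replicates of n = 300 with single chains (500
  adaptation, 300 burn-in, 1,200 kept) — coverage asserted at 4/5 and mean
  bias within 10% plus two Monte-Carlo standard errors. The full design (40
  replicates, 2,000 kept draws) gives 95% coverage for the association
  coefficient, 97.5% for the arm effect, and −6% mean relative bias;
* structure selection: 3 replicates of n = 300, all four structures fitted
  (full design: 10 replicates) — majority selection asserted. Under the
  default scenario this check fails honestly: with ~30 deaths per trial the
  generating cumulative coefficient (−0.0035 per sqrt-cell-month of area)
  is itself statistically undetectable — the true-structure fit's own 95%
  interval for it spans zero — so DIC margins between structures (a few to
  ~20 units) sit inside Monte-Carlo noise and selection is near-uniform.
  Detecting the cumulative form reliably would need a stronger generating
  association or substantially more events than the emulated trial's
  mortality produces; the generator was not re-tuned to manufacture a pass;
* attenuation: 6 replicates of n = 300 (full design: 20) — majority
  attenuation asserted.

## Known limitations

* The random-walk sampler is adequate at trial scale (hundreds of
  subjects) but mixes slowly for the baseline-spline block when events are
  very sparse; effective sample sizes should be checked via
  `diagnostics()`.
* $\sigma_w$ in the weighted structure is weakly identified when few
  events occur late in follow-up; its posterior then largely reflects the
  prior.
* The conditional-DIC convention penalises the random effects through the
  plug-in at $\bar b_i$; comparisons across packages using marginal DIC are
  not meaningful.
* LOCF comparisons use Breslow tie handling; with continuous simulated
  times ties are measure-zero, but heavily rounded external data would
  warrant Efron.
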