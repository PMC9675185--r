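# jmassoc

Bayesian joint models linking a longitudinal CD4-count trajectory to the
hazard of death, with the four most used association structures and the
machinery to choose between them.

## The problem

In HIV/TB treatment cohorts, repeated CD4 counts carry the prognostic
signal for mortality, but CD4 is an endogenous covariate: its path is
generated by the patient and truncated by death. The common fix — a Cox
model with the last observed value carried forward (LOCF) — attenuates the
association, because measurement error and the step-function imputation
both pull the estimate towards zero. A shared-random-effects joint model
fits the two processes together:

* longitudinal sub-model (square-root scale):
  `y_i(t) = (β0 + b_i0) + (β1 + b_i1) B1(t) + (β2 + b_i2) B2(t) + ε_i(t)`,
  a natural-cubic-spline mixed model with `b_i ~ N(0, D)`;
* survival sub-model:
  `h_i(t) = h0(t) exp{γ1 Arm + γ2 Age + γ3 Gender + f(m_i(·); α)}`,
  with a B-spline log baseline hazard and `f` one of four association
  structures: the **current value** `m_i(t)`, the **slopes** pair
  `(m_i(t), m_i'(t))`, the **cumulative** area `∫0^t m_i(s) ds`, or the
  **weighted cumulative** area with a normal kernel whose scale is
  estimated from the data.

Estimation is MCMC (adaptive Metropolis-within-Gibbs, written in base R);
structures are compared by DIC (smaller is better) and LPML. The package
is aimed at biostatisticians who want the full pipeline — simulation,
fitting, structure selection, classical comparators — reproducible on
synthetic data at desk scale.

## Worked example

```r
library(jmassoc)

# a synthetic trial from the default scenario: 642 subjects, 2:1 arm
# allocation, CD4 visits at 0/2/6/12/18/24 months, ~10.7% deaths
ds <- simulate_trial(trial_design(n_subjects = 200, seed = 7),
                     default_scenario("cumulative"))
ds
#> Trial dataset: 200 subjects, 765 CD4 measurements
#>   deaths: 16 (8%), follow-up <= 60 months

fit <- fit_joint_model(ds, assoc_structure("cumulative"),
                       settings = mcmc_settings(n_chains = 1, seed = 1))
summary(fit)
#> Joint model, cumulative association; 2000 posterior draws
#> ...
#> Hazard ratios, HR (95% CI):
#>   gamma_arm     0.40 (0.13-1.00)
#>   gamma_age     0.97 (0.90-1.05)
#>   gamma_gender  0.86 (0.31-2.08)
#>   alpha1        0.98 (0.96-1.00)
```

The arm hazard ratio of 0.40 recovers the generating value 0.6 within its
(wide, 16-death) credible interval. `alpha1` for the cumulative structure
is the hazard ratio per unit of *area* under the sqrt-CD4 trajectory
(sqrt-cells × months), hence its scale: a whole month spent one sqrt-CD4
unit higher multiplies the hazard by `exp(α)`. The generating value here is
`exp(-0.0035) ≈ 0.9965`. Compare
structures and run the classical comparators:

```r
fits <- lapply(c("current_value", "cumulative"), function(tag)
  fit_joint_model(ds, assoc_structure(tag),
                  settings = mcmc_settings(n_chains = 1, seed = 1)))
compare_structures(fits)      # DIC/LPML table, DIC-best marked selected
fit_tv_cox(build_counting_process(ds))  # LOCF time-varying Cox
km_estimator(ds$survival, ds$survival$arm)
```

`run_pipeline(run_config(...))` chains all of the above — simulate or read
CSVs, fit the requested structures, compare, summarise — into one report
bundle with every artifact stamped by seed.

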