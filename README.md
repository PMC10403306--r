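# cderisk

Causal analysis of dementia risk when death is a competing event, built
around an emulated target trial of smoking cessation in late midlife.

When an exposure shortens life, subjects it kills can never be diagnosed
with dementia, so "effects on dementia" split into two different questions.
`cderisk` implements both as weighted discrete-time estimators over yearly
person-time, together with a synthetic cohort generator and counterfactual
oracles so that every estimator is validated against known ground truth:

* **Total effect** — `Pr[Y_K^{a=1}] − Pr[Y_K^{a=0}]`: contrast of 20-year
  dementia risks had everyone quit versus continued smoking, deaths
  retained as competing outcomes. Estimated by an
  inverse-probability-of-treatment-weighted (IPTW) Aalen–Johansen
  cause-specific cumulative incidence,
  `R(t) = Σ_{j≤t} S(j−1) h_Y(j)`, `S(j) = Π_{m≤j}(1 − h_Y(m) − h_D(m))`.
* **Controlled direct effect (CDE)** —
  `Pr[Y_K^{a=1, d̄=0̄}] − Pr[Y_K^{a=0, d̄=0̄}]`: the same contrast had death
  been eliminated for everyone. Estimated by the complement of a
  Kaplan–Meier curve weighted by IPTW × time-varying
  inverse-probability-of-censoring-by-death (IPCW) weights,
  `w_C(t) = Π_{j≤t} 1 / P(D_j = 0 | D_{j−1} = 0, Y_{j−1} = 0, A, L̄_j)`,
  zero after death.
* **Total effect on all-cause mortality** — IPTW Kaplan–Meier with time to
  death retained beyond a dementia diagnosis; reported alongside so the
  "protection by death" pathway is visible.

Effects are reported as risk differences (percentage points) and risk
ratios at a horizon, with percentile-bootstrap confidence intervals
(subjects resampled, weight models refitted per replicate) and a
three-tier censoring-adjustment ladder (unconditional / baseline-only /
baseline + time-varying covariates).

## Worked example

```r
library(cderisk)
cfg <- dgp_config(n = 10000, seed = 2024)  # calibrated default generator
coh <- simulate_cohort(cfg)
crude_summary(coh)
#>        arm     n dementia dementia_pct death death_pct
#>   continue  3693      301          8.2  1656      44.8
#>       quit  6307      622          9.9  1471      23.3
#>    overall 10000      923          9.2  3127      31.3

fit <- cde_trial(coh, n_boot = 200, seed = 1)
fit
#> Emulated trial: smoking cessation, 10000 subjects, 20-year horizon
#>
#>  Causal effect                                              RD (pp) RD 95% CI      RR   RR 95% CI
#>  Total effect on dementia                                   1.6     (0.5, 2.7)     1.19 (1.05, 1.37)
#>  Controlled direct effect on dementia (with IPCW for death) -1.9    (-3.7, -0.1)   0.87 (0.77, 0.99)
#>  Total effect on mortality                                  -24.5   (-26.0, -22.8) 0.48 (0.46, 0.51)
```

Quitting looks *harmful* for dementia in the total-effect sense (+1.6 pp)
yet *protective* once death is eliminated (−1.9 pp): the total effect
bundles the large survival benefit (−24.5 pp mortality), which keeps
quitters alive into the high-dementia-risk years. The generator's own
intervened simulation confirms both signs are real, not artifacts:

```r
oracle_truth(cfg, n_mc = 1e5, seed = 77)
#> Oracle truth (n_mc = 1e+05, horizon = 20 years)
#>   total effect on dementia:  RD +1.36 pp (MC SE 0.064), RR 1.174
#>   CDE on dementia (no death): RD -2.44 pp (MC SE 0.049), RR 0.829
#>   total effect on mortality: RD -23.22 pp, RR 0.498
```

`summary(fit)` adds crude tables and weight diagnostics, `plot(fit)` draws
the three pairs of risk curves, and `write_trial_report(fit, dir)` emits
everything as CSV plus a plain-text report. Lower-level pieces
(`expand_person_years()`, `fit_treatment_weights()`,
`fit_censoring_weights()`, `cause_specific_risk()`, `net_risk()`,
`mortality_risk()`, `adjustment_ladder()`, `bootstrap_ci()`) are exported
for custom analyses; see the vignette in `vignettes/` for the model,
assumptions, and design choices.

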