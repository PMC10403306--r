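---
title: "Total and controlled direct effects on dementia risk when death competes"
author: "cderisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total and controlled direct effects on dementia risk when death competes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cderisk)
```

## The problem

When dementia is the outcome of a cohort study, death from other causes is a
competing event: a subject who dies dementia-free can never be diagnosed
afterwards. Exposures that shorten life therefore mechanically "protect"
against dementia, and a single exposure can look harmful or protective
depending on which causal question is asked. `cderisk` implements two
well-defined questions for a binary baseline exposure (quitting versus
continuing smoking in late midlife) and keeps them clearly separated:

* **Total effect** — the contrast of 20-year dementia risks had everyone
  quit versus had everyone continued. Deaths are part of the outcome
  process: subjects who die stay in the denominator and never enter the
  numerator. The estimand is the cause-specific cumulative incidence
  ("crude risk"), and the estimator is an IPTW-weighted discrete-time
  Aalen–Johansen curve.
* **Controlled direct effect (CDE)** — the same contrast in a hypothetical
  world where death is eliminated for everyone. Death now acts as
  censoring, and identification needs exchangeability for
  censoring-by-death given measured shared causes of death and dementia.
  The estimator is the complement of a Kaplan–Meier curve weighted by the
  product of treatment weights and time-varying
  inverse-probability-of-censoring-by-death weights.

Because the total effect bundles a pathway through survival, the package
always reports the total effect on all-cause mortality alongside (with
time to death counted past a dementia diagnosis), so a reader can judge how
much "protection by death" is in play.

## Data model and timing conventions

A cohort is one row per subject: exposure `a`, baseline covariates (age,
sex, APOE-e4 carrier status, education in four levels), yearly time-varying
covariates (systolic blood pressure, body-mass index, an absorbing
comorbidity indicator), `dementia_year`, `death_year`, and the
administrative horizon (20 years by default). Time is discrete in years
1..K; a continuous event time u maps to year `ceiling(u)`.

Three conventions matter and are used consistently by the expansion, the
simulator, the weights and the estimators:

* Dementia cannot be recorded after death, but death after dementia is
  allowed (semicompeting structure), and mortality follow-up continues past
  the diagnosis.
* Within a year, dementia is recorded before death: only death by year
  t−1 blocks dementia at t, so `y` and `d` may both be 1 on the same
  person-year row. Same-year dementia+death rows count as dementia events
  in the dementia hazard and as deaths in the all-cause hazard, but not in
  the death-before-dementia hazard.
* Missing time-varying covariates are carried forward from the last
  observed year (an error if year 1 is missing). This is the minimal
  explicit rule; no imputation is attempted.

`expand_person_years()` produces the long table with the two risk-set
flags: `at_risk_dementia` (alive and dementia-free at the year's start) and
`at_risk_death` (alive at the year's start, dementia status irrelevant).

## Weights

Treatment weights are `1 / P(A = a | age, sex, APOE-e4, education)` from a
logistic model; both components default to *unstabilized* weights, matching
the estimators' verbal definitions, with stabilization as an explicit
option (stabilizing and truncating together changes the implied target
population, so it is never silent). Censoring weights come from a pooled
logistic model for death fitted on person-years that are alive *and
dementia-free* at the year's start — the weights serve the dementia risk
sets, so post-dementia person-years are excluded from fitting. The year-t
weight is the telescoping product of inverse fitted yearly survival
probabilities through year t, and is zero for subjects dead by t. Under
the dementia-first convention, dementia and death indicators are
conditionally independent within a year given the modelled history, so
applying the through-year-t product to the year-t risk set leaves the
weighted hazard unbiased for the death-free-world hazard.

The default time trend in the censoring model is linear + quadratic in the
year index; year indicators are available (`time_terms = "indicators"`),
exact in small saturated fixtures but unstable when some years hold few
deaths. Fitted probabilities below `1e-8` trigger a positivity warning
rather than silent clipping, since positivity for remaining alive is a
substantive identification condition, not a numerical nuisance. An
arm-year whose weighted risk set empties truncates the curve with an
explicit flag rather than imputing.

With fully saturated discrete models, the censoring-weighted risk set
telescopes back to the cohort size exactly — until dementia events deplete
it, because the weights resurrect deaths, not dementia cases. The test
suite asserts the exact identity on deaths-only fixtures.

## The adjustment ladder and the bootstrap

`adjustment_ladder()` re-estimates the CDE under three censoring
assumptions — (1) unconditional (intercept + time model), (2) baseline
covariates only, (3) baseline + time-varying covariates — holding
everything else fixed. On generated data with a strong shared time-varying
cause, tier 1 is visibly biased while tier 3 recovers the oracle truth;
the suite checks the ordering in 50 replicates.

Confidence intervals are percentile bootstrap over subjects (never
person-years), 500 samples by default. Weight models are refitted inside
every replicate, the conservative reading that propagates weight-estimation
uncertainty; `refit_weights = FALSE` reuses the original weights for
comparison. Replicates with an empty exposure arm are dropped and counted,
with a hard warning above 5%. For the total-effect and mortality
statistics the bootstrap uses a subject-level computation of the same
weighted hazards (reverse cumulative sums instead of person-year
expansion); the suite asserts bit-level agreement with the estimator path,
so it is an optimization, not a second estimator.

## What the generator emulates

`dgp_config()` parameterizes a discrete-time structural model with the
causal topology above: confounded exposure assignment, an absorbing
comorbidity process and drifting SBP/BMI as shared causes, and yearly
logistic hazards for dementia and death. Defaults are calibration choices,
not estimates: they target roughly 62% quitters, 8.8% 20-year dementia and
31.5% 20-year mortality (published cohort-scale margins), a strongly
protective exposure effect on death, and a modest directly protective
effect on dementia. Under these defaults the estimated total effect of
quitting on dementia is *positive* (about +1.3 pp in truth) while the CDE
is *negative* (about −2.5 pp): the headline sign-separation phenomenon.
The within-follow-up rise of the death hazard is carried by covariate
drift and comorbidity accumulation rather than an explicit year term; the
dementia hazard has a steep year trend, concentrating diagnoses late in
follow-up, which is what makes the survival pathway visible at all.

The hazard models are logistic in exactly the covariates the default
weight models use, so correct specification — and therefore parameter
recovery — is achievable by design; `misspecify = TRUE` adds an omitted
age-by-comorbidity interaction for robustness experiments. Potential
outcomes under the four regimes (quit/continue × death
eliminated or not) are generated from common random draws, making
consistency exact and regime contrasts variance-reduced.

What the generator does *not* emulate: loss to follow-up (follow-up is
complete, as in registry-linked cohorts; an optional `dropout_year` is
treated as administrative end only), measurement error in exposure or
outcome, continuous event times, and calendar-time structure. Passing
tests therefore demonstrate estimator correctness under the stated model,
not robustness to those features of real data.

## Oracles and problem sizes

Truth is defined by the generator's own intervened simulation
(`oracle_truth()`, cached by configuration digest), never by an estimator;
`enumerate_small_cohort()` gives exact counting answers for tiny cohorts,
against which the estimators must agree to machine precision over every
event pattern with up to 4 subjects and 2 years. The test suite sizes are
chosen to keep Monte-Carlo error well below the asserted tolerances:
recovery at n = 50,000 against a 200,000-draw oracle, sign separation at
n = 100,000, ladder ordering with 50 replicates of n = 20,000, and
bootstrap coverage with 200 replicates of n = 2,000 at 200 bootstrap
samples.

## A worked run

```{r, eval = FALSE}
cfg <- dgp_config(n = 20000, seed = 2024)
coh <- simulate_cohort(cfg)
fit <- cde_trial(coh, n_boot = 500, seed = 1)
summary(fit)
plot(fit)
oracle_truth(cfg, n_mc = 2e5, seed = 77)
```

## Known limitations

* The censoring-weight estimator inherits IPCW's variance sensitivity to
  near-violations of positivity; truncation is available but shifts the
  estimand.
* Only inverse-probability weighting is implemented; g-formula and doubly
  robust estimators are out of scope, as are separable effects and
  survivor-average contrasts.
* Cause-specific hazard-ratio regression is deliberately absent: hazard
  contrasts condition on survival and do not compare the same individuals
  under both exposures, so they answer neither of the two questions above.
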