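test_that("treatment weights match closed-form saturated MLEs", {
  # single binary covariate; X=1 stratum: 4/5 exposed; X=0 stratum: 2/4
  coh <- make_cohort(NA, NA, a = c(1, 1, 1, 1, 0, 1, 1, 0, 0), K = 2,
                     covariates = data.frame(x = c(1, 1, 1, 1, 1, 0, 0, 0, 0)))
  tw <- fit_treatment_weights(coh, covariates = "x")
  expect_equal(tw$w[1:4], rep(1.25, 4), tolerance = 1e-6)
  expect_equal(tw$w[5], 5, tolerance = 1e-6)
  expect_equal(tw$w[6:9], rep(2, 4), tolerance = 1e-6)
  # mean unstabilized weight = number of exposure levels, exactly
  expect_equal(mean(tw$w), 2, tolerance = 1e-8)

  # exposure independent of covariates at P = 1/2: all weights ~ 2
  set.seed(8)
  coh2 <- make_cohort(NA, NA, a = rep(c(0, 1), 50), K = 2,
                      covariates = data.frame(x = rbinom(100, 1, .5)))
  tw2 <- fit_treatment_weights(coh2, covariates = "x")
  expect_true(all(abs(tw2$w - 2) < 0.35))

  # stabilized weights: numerator is the marginal exposure frequency
  tws <- fit_treatment_weights(coh, covariates = "x", stabilized = TRUE)
  expect_equal(mean(tws$w), 1, tolerance = 0.01)
})

test_that("censoring weights follow the telescoping definition", {
  # no deaths: all censoring weights are exactly one
  coh <- make_cohort(c(2, NA, NA), NA, a = c(1, 0, 1), K = 3)
  py <- expand_person_years(coh)
  # (a death model without deaths is flagged as near-separated; expected)
  expect_warning(cw <- fit_censoring_weights(py, baseline = NULL,
                                             timevarying = NULL),
                 "separation")
  expect_equal(cw$w_c[py$at_risk_dementia == 1],
               rep(1, sum(py$at_risk_dementia)))

  # a subject dead by year t has weight zero from the death year on
  coh2 <- make_cohort(NA, c(3, NA, NA, NA), a = c(1, 1, 0, 0), K = 5)
  py2 <- expand_person_years(coh2)
  cw2 <- suppressWarnings(
    fit_censoring_weights(py2, baseline = NULL, timevarying = NULL,
                          time_terms = "indicators"))  # sparse-year fit
  dead_row <- py2$.subj_row == 1 & py2$year == 3
  expect_equal(cw2$w_c[dead_row], 0)
  expect_equal(sum(py2$.subj_row == 1), 3)  # no person-years after death

  # two-year toy cohort, empirical survival 1/2 each year: survivor w_C(2)=4
  coh3 <- make_cohort(NA, c(1, 1, 2, NA), a = 1, K = 2)
  py3 <- expand_person_years(coh3)
  cw3 <- fit_censoring_weights(py3, baseline = NULL, timevarying = NULL,
                               time_terms = "indicators")
  expect_equal(cw3$w_c[py3$.subj_row == 4], c(2, 4), tolerance = 1e-6)
})

test_that("combining weights is an elementwise product with identity defaults", {
  coh <- random_cohort(30, 4, seed = 3)
  py <- expand_person_years(coh)
  coh$x <- rbinom(30, 1, 0.5)
  tw <- fit_treatment_weights(coh, covariates = "x")
  cw <- fit_censoring_weights(py, baseline = NULL, timevarying = NULL)
  ws <- combine_weights(tw, cw, py)
  expect_equal(ws$w, tw$w[py$.subj_row] * cw$w_c)
  # identity when one side is missing
  expect_equal(combine_weights(NULL, cw, py)$w, cw$w_c)
  expect_equal(combine_weights(tw, NULL, py)$w, tw$w[py$.subj_row])
  # zero-after-death propagates through the product
  dead <- !is.na(coh$death_year[py$.subj_row]) &
    py$year >= coh$death_year[py$.subj_row] & py$at_risk_dementia == 1
  expect_true(all(ws$w[dead] == 0))
})

test_that("weight diagnostics summarize and truncate as requested", {
  d0 <- diagnose_weights(rep(1.7, 50))
  expect_equal(d0$before$sd, 0)
  expect_equal(d0$n_capped, 0)

  w <- c(rep(1, 99), 50)
  expect_equal(diagnose_weights(w, 100)$w, w)       # 100th pct = identity
  d99 <- diagnose_weights(w, 98)
  expect_equal(d99$n_capped, 1L)                    # one extreme weight capped
  expect_lt(max(d99$w), 50)
  expect_equal(d99$before$max, 50)
})

test_that("weights are invariant to subject order and cohort duplication", {
  coh <- random_cohort(60, 5, seed = 13)
  coh$x <- rbinom(60, 1, 0.4)
  tw <- fit_treatment_weights(coh, covariates = "x")
  perm <- sample(60)
  cohp <- coh[perm, ]
  twp <- fit_treatment_weights(cohp, covariates = "x")
  expect_equal(twp$w, tw$w[perm], tolerance = 1e-10)
  # duplicating the whole cohort leaves fitted probabilities unchanged
  dup <- rbind(coh, coh)
  dup$subject_id <- seq_len(nrow(dup))
  twd <- fit_treatment_weights(dup, covariates = "x")
  expect_equal(twd$w, rep(tw$w, 2), tolerance = 1e-8)
})

test_that("unit weights reduce every estimator to its unweighted form", {
  coh <- random_cohort(80, 6, seed = 19)
  py <- expand_person_years(coh)
  ones <- rep(1, nrow(py))
  for (f in list(cause_specific_risk, net_risk, mortality_risk)) {
    expect_identical(f(py, NULL, arm = 1)$risk, f(py, ones, arm = 1)$risk)
  }
})

test_that("separation and positivity problems are surfaced as warnings", {
  coh <- make_cohort(NA, NA, a = c(rep(1, 10), rep(0, 10)), K = 2,
                     covariates = data.frame(x = c(rep(1, 10), rep(0, 10))))
  expect_warning(fit_treatment_weights(coh, covariates = "x"), "separation")
})
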