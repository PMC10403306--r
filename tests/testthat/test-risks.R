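test_that("cause-specific risk matches hand enumeration with competing deaths", {
  # n=4: one dementia in year 1, one death in year 2, K=2
  coh <- make_cohort(c(1, NA, NA, NA), c(NA, 2, NA, NA), a = 1, K = 2)
  py <- expand_person_years(coh)
  r <- cause_specific_risk(py)
  expect_equal(r$risk[r$year == 1], 0.25)
  expect_equal(r$risk[r$year == 2], 0.25)

  # without deaths the AJ estimate is the empirical cumulative proportion
  coh2 <- make_cohort(c(1, 2, 3, NA, NA), NA, a = 1, K = 3)
  py2 <- expand_person_years(coh2)
  r2 <- cause_specific_risk(py2)
  expect_equal(r2$risk[-1], c(1, 2, 3) / 5)

  # scale invariance: multiplying all weights by c > 0 changes nothing
  py3 <- expand_person_years(random_cohort(50, 5, seed = 21))
  w <- runif(nrow(py3), 0.5, 2)
  expect_equal(cause_specific_risk(py3, w)$risk,
               cause_specific_risk(py3, 7.3 * w)$risk, tolerance = 1e-12)
})

test_that("net risk behaves as a weighted KM complement", {
  # zero deaths and unit weights: net risk == cause-specific risk
  coh <- make_cohort(c(1, 2, NA, NA, NA, 3), NA, a = 1, K = 4)
  py <- expand_person_years(coh)
  expect_equal(net_risk(py)$risk, cause_specific_risk(py)$risk,
               tolerance = 1e-12)

  # single subject with dementia in year 1: risk 1 immediately
  py1 <- expand_person_years(make_cohort(1, NA, a = 1, K = 2))
  expect_equal(net_risk(py1)$risk[2], 1)

  # with any competing hazard, net risk >= crude risk at every year
  for (seed in 1:6) {
    pyr <- expand_person_years(random_cohort(200, 6, seed + 100))
    nr <- net_risk(pyr)$risk
    cr <- cause_specific_risk(pyr)$risk
    ok <- !is.na(nr) & !is.na(cr)
    expect_true(all(nr[ok] - cr[ok] >= -1e-12))
  }
})

test_that("mortality risk keeps post-diagnosis follow-up", {
  # dementia year 1, death year 3: mortality risk jumps only at year 3
  py <- expand_person_years(make_cohort(1, 3, a = 1, K = 4))
  r <- mortality_risk(py)
  expect_equal(r$risk[r$year == 2], 0)
  expect_equal(r$risk[r$year == 3], 1)

  # n=2, deaths in years 1 and 2
  py2 <- expand_person_years(make_cohort(NA, c(1, 2), a = 1, K = 2))
  r2 <- mortality_risk(py2)
  expect_equal(r2$risk[-1], c(0.5, 1))

  # no deaths: risk identically zero
  py3 <- expand_person_years(make_cohort(c(2, NA), NA, a = 1, K = 3))
  expect_equal(mortality_risk(py3)$risk, rep(0, 4))
})

test_that("dementia, death-before-dementia and survival partition unity", {
  for (seed in 1:8) {
    py <- expand_person_years(random_cohort(120, 7, seed))
    w <- runif(nrow(py), 0.2, 3)
    ry <- cause_specific_risk(py, w)$risk
    rd <- death_before_dementia_risk(py, w)$risk
    h <- hazard_series(py, w)
    S <- c(1, cumprod(1 - h$h_y - h$h_d))
    ok <- !is.na(ry)
    expect_equal((ry + rd + S)[ok], rep(1, sum(ok)), tolerance = 1e-12)
  }
})

test_that("risk curves are monotone, bounded, and start at zero", {
  for (seed in 1:5) {
    py <- expand_person_years(random_cohort(60, 5, seed + 30, p_dth = 0.6))
    for (f in list(cause_specific_risk, net_risk, mortality_risk)) {
      r <- f(py)$risk
      r <- r[!is.na(r)]
      expect_equal(r[1], 0)
      expect_true(all(diff(r) >= -1e-15))
      expect_true(all(r >= 0 & r <= 1))
    }
  }
})

test_that("unit-weight estimators agree with exhaustive counting oracles", {
  states <- subject_states(3)
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    pick <- states[sample(length(states), n, replace = TRUE)]
    coh <- make_cohort(vapply(pick, `[`, 0, 1), vapply(pick, `[`, 0, 2),
                       a = 1, K = 3)
    py <- expand_person_years(coh)
    oracle <- enumerate_small_cohort(coh)
    expect_curve_equal(cause_specific_risk(py), oracle$crude)
    expect_curve_equal(net_risk(py), oracle$net_unit)
    expect_curve_equal(mortality_risk(py), oracle$mortality)
    expect_curve_equal(death_before_dementia_risk(py),
                       oracle$death_before_dementia)
  }
})

test_that("curves truncate with a flag when the risk set empties", {
  coh <- make_cohort(NA, c(1, 1), a = 1, K = 3)  # everyone dies in year 1
  py <- expand_person_years(coh)
  r <- cause_specific_risk(py)
  expect_true(is.na(r$risk[r$year == 2]))
  expect_true(any(r$flag == "empty risk set"))
})

test_that("unweighted AJ and KM curves match the survival package", {
  skip_if_not_installed("survival")
  for (seed in 1:20) {
    K <- sample(4:10, 1)
    coh <- random_cohort(50, K, seed + 500, p_dth = 0.5)
    py <- expand_person_years(coh)
    dem <- ifelse(is.na(coh$dementia_year), Inf, coh$dementia_year)
    dth <- ifelse(is.na(coh$death_year), Inf, coh$death_year)

    t1 <- pmin(dem, dth, K)
    st <- ifelse(dem <= pmin(dth, K), 1, ifelse(dth <= K, 2, 0))
    sf <- survival::survfit(
      survival::Surv(t1, factor(st, 0:2, c("censor", "dementia", "death"))) ~ 1)
    aj <- summary(sf, times = 1:K, extend = TRUE)$pstate[, "dementia"]
    expect_equal(cause_specific_risk(py)$risk[-1], aj, tolerance = 1e-10)

    t2 <- pmin(dth, K)
    sf2 <- survival::survfit(survival::Surv(t2, as.numeric(dth <= K)) ~ 1)
    km <- 1 - summary(sf2, times = 1:K, extend = TRUE)$surv
    expect_equal(mortality_risk(py)$risk[-1], km, tolerance = 1e-10)

    t3 <- pmin(dem, dth, K)
    sf3 <- survival::survfit(
      survival::Surv(t3, as.numeric(dem <= pmin(dth, K))) ~ 1)
    nr <- 1 - summary(sf3, times = 1:K, extend = TRUE)$surv
    expect_equal(net_risk(py)$risk[-1], nr, tolerance = 1e-10)
  }
})
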