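mk_curve <- function(risks, estimand = "total_effect_dementia", arm = 1) {
  structure(data.frame(estimand = estimand, arm = arm,
                       year = seq_along(risks) - 1, risk = risks,
                       atrisk_w = 1, flag = ""),
            class = c("risk_curve", "data.frame"))
}

test_that("risk contrasts are arithmetic on the horizon risks", {
  c1 <- mk_curve(c(0, 0.05, 0.096))
  c0 <- mk_curve(c(0, 0.04, 0.074), arm = 0)
  est <- risk_contrast(c1, c0)
  expect_equal(est$rd, 2.2, tolerance = 1e-9)
  expect_equal(est$rr, 0.096 / 0.074, tolerance = 1e-9)
  expect_equal(round(est$rr, 2), 1.30)

  est2 <- risk_contrast(mk_curve(c(0, 0.5)), mk_curve(c(0, 0.25), arm = 0))
  expect_equal(est2$rd, 25)
  expect_equal(est2$rr, 2)

  # identical curves: null contrast
  est3 <- risk_contrast(c1, c1)
  expect_equal(est3$rd, 0)
  expect_equal(est3$rr, 1)

  # zero reference risk: RR undefined and flagged
  est4 <- risk_contrast(mk_curve(c(0, 0.1)), mk_curve(c(0, 0), arm = 0))
  expect_true(is.na(est4$rr))
  expect_match(est4$flag, "undefined")
})

test_that("bootstrap is deterministic given a seed and degenerate on constant data", {
  coh <- simulate_cohort(dgp_config(n = 600, K = 6, seed = 51))
  b1 <- bootstrap_ci(coh, "total", n_boot = 40, seed = 7)
  b2 <- bootstrap_ci(coh, "total", n_boot = 40, seed = 7)
  expect_identical(b1$rd_lo, b2$rd_lo)
  expect_identical(attr(b1, "replicates"), attr(b2, "replicates"))
  # point estimate lies inside its own percentile interval
  expect_true(b1$rd_lo <= b1$rd && b1$rd <= b1$rd_hi)

  # a cohort of identical subjects in each arm gives a width-zero interval
  cohd <- make_cohort(rep(c(2, NA), each = 20), NA,
                      a = rep(c(1, 0), each = 20), K = 3)
  cohd$age0 <- 60; cohd$sex <- 1; cohd$apoe4 <- 0; cohd$education <- 2
  bd <- suppressWarnings(bootstrap_ci(cohd, "total", n_boot = 30, seed = 3))
  expect_equal(bd$rd_hi - bd$rd_lo, 0, tolerance = 1e-9)
})

test_that("subject-level bootstrap fast path equals the estimator path", {
  coh <- simulate_cohort(dgp_config(n = 800, K = 8, seed = 61))
  tv <- grep("^(sbp|bmi|comorb)_", names(coh))
  slow <- bootstrap_ci(coh[-tv], "total", n_boot = 25, seed = 9,
                       truncation_percentile = 100)  # disables the fast path
  fast <- bootstrap_ci(coh, "total", n_boot = 25, seed = 9)
  expect_equal(attr(fast, "replicates"), attr(slow, "replicates"),
               tolerance = 1e-12)
  slow_m <- bootstrap_ci(coh[-tv], "mortality", n_boot = 25, seed = 9,
                         truncation_percentile = 100)
  fast_m <- bootstrap_ci(coh, "mortality", n_boot = 25, seed = 9)
  expect_equal(attr(fast_m, "replicates"), attr(slow_m, "replicates"),
               tolerance = 1e-12)
})

test_that("adjustment tiers agree when censoring is unconditionally exchangeable", {
  # no shared causes and no baseline effects on death: every tier unbiased
  cfg <- dgp_config(n = 30000, K = 8, seed = 71)
  cfg$alpha[c("age", "sex", "comorb", "sbp", "bmi")] <- 0
  coh <- simulate_cohort(cfg)
  lad <- adjustment_ladder(coh)
  expect_equal(lad$rd[1], lad$rd[3], tolerance = 0.6)  # within MC error, pp
  expect_equal(lad$rd[2], lad$rd[3], tolerance = 0.6)
  expect_equal(lad$tier,
               c("unconditional", "baseline_only", "baseline_plus_timevarying"))
})

test_that("the emulated-trial report runs end to end and is reproducible", {
  coh <- simulate_cohort(dgp_config(n = 2000, seed = 81))
  t0 <- Sys.time()
  fit <- cde_trial(coh, n_boot = 20, seed = 4)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)

  expect_s3_class(fit, "cde_trial")
  expect_equal(fit$estimates$estimand,
               c("total_effect_dementia", "cde_dementia", "mortality"))
  out <- capture.output(print(fit))
  expect_true(any(grepl("Total effect on dementia", out)))
  expect_true(any(grepl(
    "Controlled direct effect on dementia (with IPCW for death)", out,
    fixed = TRUE)))
  expect_true(any(grepl("Total effect on mortality", out)))
  expect_length(coef(fit), 3)

  d1 <- tempfile(); d2 <- tempfile()
  write_trial_report(fit, d1)
  fit2 <- cde_trial(coh, n_boot = 20, seed = 4)
  write_trial_report(fit2, d2)
  for (f in c("estimates.csv", "crude_summary.csv", "risk_curves.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("plot methods draw without error", {
  coh <- simulate_cohort(dgp_config(n = 500, K = 6, seed = 91))
  fit <- cde_trial(coh)
  pdf(NULL)
  on.exit(dev.off())
  expect_no_error(plot(fit))
  expect_no_error(plot(fit$curves$total_a1))
})
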