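# Ground truth for the synthetic data-generating process: large-n intervened
# simulation (the estimand definitions run forward through the model) and
# exact small-cohort enumeration used to validate the estimators.

.oracle_cache <- new.env(parent = emptyenv())

oracle_key <- function(config, horizon, n_mc, seed) {
  paste(collapse = "|", c(format(unlist(config), digits = 17),
                          horizon, n_mc, seed))
}

#' True counterfactual risks and effects under a DGP configuration
#'
#' Simulates `n_mc` subjects under each of the four intervened regimes
#' (quit / continue, each factual-death and death-eliminated), with common
#' random numbers across regimes, and reads off the true regime-specific
#' dementia risks at the horizon.  The total effect contrasts the
#' factual-death regimes; the controlled direct effect contrasts the
#' death-eliminated regimes; the mortality effect contrasts death risks.
#' Results are cached in-session by configuration digest.
#'
#' @param config a [dgp_config()] object.
#' @param horizon risk horizon in years (defaults to `config$K`).
#' @param n_mc Monte-Carlo sample size.
#' @param seed seed for the oracle draw stream (independent of
#'   `config$seed` so the truth is not computed from the analysed cohort).
#' @return an object of class `oracle_truth`: regime risks, `total_rd`,
#'   `total_rr`, `cde_rd`, `cde_rr`, `mortality_rd`, `mortality_rr` (RDs in
#'   percentage points), paired Monte-Carlo standard errors (`total_rd_se`,
#'   `cde_rd_se`, on the percentage-point scale), `n_mc`, `seed`.
#' @examples
#' tr <- oracle_truth(dgp_config(), n_mc = 20000, seed = 9)
#' tr$total_rd; tr$cde_rd
#' @export
oracle_truth <- function(config, horizon = config$K, n_mc = 5e5, seed = 1) {
  key <- oracle_key(config, horizon, n_mc, seed)
  if (!is.null(.oracle_cache[[key]])) return(.oracle_cache[[key]])
  cfg <- config
  cfg$seed <- seed
  draws <- dgp_draws(cfg, n = n_mc)
  run <- function(a, nodeath) {
    sim <- dgp_engine(cfg, draws, a_override = a, eliminate_death = nodeath,
                      keep_history = FALSE)
    list(dem = !is.na(sim$dementia_year) & sim$dementia_year <= horizon,
         dth = !is.na(sim$death_year) & sim$death_year <= horizon)
  }
  r11 <- run(1, FALSE); r00 <- run(0, FALSE)
  e11 <- run(1, TRUE);  e00 <- run(0, TRUE)
  risk <- function(x) mean(x)
  paired_se <- function(x1, x0) 100 * stats::sd(x1 - x0) / sqrt(n_mc)
  ratio <- function(p1, p0) if (p0 > 0) p1 / p0 else NA_real_
  out <- structure(list(
    risk_a1 = risk(r11$dem), risk_a0 = risk(r00$dem),
    risk_a1_nodeath = risk(e11$dem), risk_a0_nodeath = risk(e00$dem),
    death_a1 = risk(r11$dth), death_a0 = risk(r00$dth),
    total_rd = 100 * (risk(r11$dem) - risk(r00$dem)),
    total_rr = ratio(risk(r11$dem), risk(r00$dem)),
    cde_rd = 100 * (risk(e11$dem) - risk(e00$dem)),
    cde_rr = ratio(risk(e11$dem), risk(e00$dem)),
    mortality_rd = 100 * (risk(r11$dth) - risk(r00$dth)),
    mortality_rr = ratio(risk(r11$dth), risk(r00$dth)),
    total_rd_se = paired_se(r11$dem, r00$dem),
    cde_rd_se = paired_se(e11$dem, e00$dem),
    mortality_rd_se = paired_se(r11$dth, r00$dth),
    horizon = horizon, n_mc = n_mc, seed = seed
  ), class = "oracle_truth")
  .oracle_cache[[key]] <- out
  out
}

#' @describeIn oracle_truth total-effect fields only.
#' @export
true_total_effect <- function(config, horizon = config$K, n_mc = 5e5, seed = 1) {
  tr <- oracle_truth(config, horizon, n_mc, seed)
  tr[c("risk_a1", "risk_a0", "total_rd", "total_rr", "total_rd_se",
       "horizon", "n_mc")]
}

#' @describeIn oracle_truth controlled-direct-effect fields only.
#' @export
true_cde <- function(config, horizon = config$K, n_mc = 5e5, seed = 1) {
  tr <- oracle_truth(config, horizon, n_mc, seed)
  tr[c("risk_a1_nodeath", "risk_a0_nodeath", "cde_rd", "cde_rr",
       "cde_rd_se", "horizon", "n_mc")]
}

#' @export
print.oracle_truth <- function(x, ...) {
  cat(sprintf("Oracle truth (n_mc = %s, horizon = %d years)\n",
              format(x$n_mc, big.mark = ","), x$horizon))
  cat(sprintf("  total effect on dementia:  RD %+.2f pp (MC SE %.3f), RR %.3f\n",
              x$total_rd, x$total_rd_se, x$total_rr))
  cat(sprintf("  CDE on dementia (no death): RD %+.2f pp (MC SE %.3f), RR %.3f\n",
              x$cde_rd, x$cde_rd_se, x$cde_rr))
  cat(sprintf("  total effect on mortality: RD %+.2f pp, RR %.3f\n",
              x$mortality_rd, x$mortality_rr))
  invisible(x)
}

#' Exact risks on a small cohort by exhaustive counting
#'
#' Brute-force oracle for the estimators: computes the crude dementia risk,
#' the unit-weight net risk, the net risk under saturated (per-arm,
#' per-year empirical survival) censoring weights, and the all-cause
#' mortality risk, by explicit counting loops over subjects.  Intended for
#' tiny cohorts (n of a few, short horizons) where the counting argument is
#' self-evidently correct; estimators must agree to machine precision.
#'
#' @param cohort a cohort data frame.
#' @param horizon years of follow-up.
#' @param by_arm compute within one arm only (0/1), or pooled (`NULL`).
#' @return list of numeric vectors over years 1..horizon: `crude`,
#'   `net_unit`, `net_saturated`, `mortality`, `death_before_dementia`.
#' @export
enumerate_small_cohort <- function(cohort, horizon = NULL, by_arm = NULL) {
  K <- horizon %||% max(cohort$admin_end)
  if (!is.null(by_arm)) cohort <- cohort[cohort$a == by_arm, , drop = FALSE]
  n <- nrow(cohort)
  dem <- ifelse(is.na(cohort$dementia_year), Inf, cohort$dementia_year)
  dth <- ifelse(is.na(cohort$death_year), Inf, cohort$death_year)
  crude <- numeric(K); mort <- numeric(K); dpre <- numeric(K)
  net_u <- numeric(K); net_s <- numeric(K)
  surv_u <- 1; surv_s <- 1
  for (t in seq_len(K)) {
    crude[t] <- sum(dem <= t) / n
    mort[t] <- sum(dth <= t) / n
    dpre[t] <- sum(dth <= t & dem > dth) / n
    # unit-weight KM: risk set = alive and dementia-free at start of year t
    rs <- sum(dem >= t & dth >= t)
    ev <- sum(dem == t)
    if (rs > 0) surv_u <- surv_u * (1 - ev / rs)
    net_u[t] <- 1 - surv_u
    # Saturated censoring weights (per-year empirical survival): every
    # subject still at risk in year t has been at risk in all years 1..t,
    # so the cumulative weight is common to the whole risk set and cancels
    # from the hazard; subjects dying in year t carry weight zero.  The
    # weighted hazard therefore equals the dementia events among year-t
    # survivors over the count of year-t survivors.
    surv_count <- sum(dem >= t & dth > t)
    ev_s <- sum(dem == t & dth > t)
    if (surv_count > 0) surv_s <- surv_s * (1 - ev_s / surv_count)
    net_s[t] <- 1 - surv_s
  }
  list(crude = crude, net_unit = net_u, net_saturated = net_s,
       mortality = mort, death_before_dementia = dpre)
}
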