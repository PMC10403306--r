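# Fixture constructors used across the suite.  Everything is built in code;
# event years use NA for "never".

make_cohort <- function(dementia = NA, death = NA, a = NULL, K = 3,
                        covariates = NULL) {
  n <- max(length(dementia), length(death), length(a %||% 1))
  dementia <- rep_len(dementia, n)
  death <- rep_len(death, n)
  coh <- data.frame(subject_id = seq_len(n),
                    a = rep_len(a %||% rep(c(0, 1), length.out = n), n),
                    dementia_year = dementia, death_year = death,
                    admin_end = K)
  if (!is.null(covariates)) coh <- cbind(coh, covariates)
  coh
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A cohort with exact per-arm sizes and event counts (events all in year 1,
# death in year K for dementia cases that also die -- counts are what matter).
counts_cohort <- function(n0, dem0, dth0, n1, dem1, dth1, K = 20) {
  arm <- function(n, ndem, ndth, a) {
    dem <- rep(NA_integer_, n)
    dth <- rep(NA_integer_, n)
    dem[seq_len(ndem)] <- 1L
    dth[seq_len(ndth)] <- K  # overlap: dementia cases may also die later
    data.frame(a = a, dementia_year = dem, death_year = dth, admin_end = K)
  }
  coh <- rbind(arm(n0, dem0, dth0, 0), arm(n1, dem1, dth1, 1))
  coh$subject_id <- seq_len(nrow(coh))
  coh
}

# Random small cohort with valid semicompeting event structure.
random_cohort <- function(n, K, seed, p_dem = 0.35, p_dth = 0.4) {
  set.seed(seed)
  dem <- ifelse(stats::runif(n) < p_dem, sample.int(K, n, replace = TRUE), NA)
  dth <- ifelse(stats::runif(n) < p_dth, sample.int(K, n, replace = TRUE), NA)
  swap <- !is.na(dem) & !is.na(dth) & dem > dth
  dem[swap] <- NA
  make_cohort(dem, dth, a = stats::rbinom(n, 1, 0.5), K = K)
}

# All distinct per-subject event states for horizon K: (dementia, death)
# with dementia <= death; NA = never.
subject_states <- function(K) {
  st <- list(c(NA, NA))
  for (d in seq_len(K)) st <- c(st, list(c(NA, d)))
  for (y in seq_len(K)) {
    st <- c(st, list(c(y, NA)))
    for (d in y:K) st <- c(st, list(c(y, d)))
  }
  st
}

# Compare a risk_curve to an oracle vector over years 1..K, skipping years
# the estimator flags as truncated (empty risk set).
expect_curve_equal <- function(curve, oracle, tol = 1e-12) {
  est <- curve$risk[curve$year >= 1]
  ok <- !is.na(est)
  expect_equal(est[ok], oracle[ok], tolerance = tol)
}
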