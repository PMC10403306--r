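# Weighted discrete-time risk estimators.  All three estimands are built
# from weighted yearly hazards over explicit risk sets, so the
# Aalen-Johansen (cause-specific cumulative incidence) and Kaplan-Meier
# (net risk, all-cause mortality) forms are directly comparable and exactly
# reproducible on year-discrete data.

resolve_weights <- function(weights, py) {
  if (is.null(weights)) return(rep(1, nrow(py)))
  if (inherits(weights, "weight_set")) return(weights$w)
  if (inherits(weights, "iptw")) return(weights$w[py$.subj_row])
  if (is.numeric(weights) && length(weights) == nrow(py)) return(weights)
  stop("weights must be NULL, a weight_set, an iptw object, or a numeric ",
       "vector with one entry per person-year row")
}

# Weighted event totals and risk-set sizes per year over a row subset.
year_sums <- function(year, w, events, K) {
  m <- cbind(den = w)
  for (nm in names(events)) m <- cbind(m, w * events[[nm]])
  colnames(m) <- c("den", names(events))
  s <- rowsum(m, year)
  out <- matrix(0, K, ncol(m), dimnames = list(NULL, colnames(m)))
  out[as.integer(rownames(s)), ] <- s
  lapply(seq_len(ncol(out)), function(j) out[, j]) |>
    stats::setNames(colnames(out))
}

new_risk_curve <- function(estimand, arm, risk, atrisk, K, flag) {
  structure(data.frame(estimand = estimand,
                       arm = arm,
                       year = 0:K,
                       risk = c(0, risk),
                       atrisk_w = c(atrisk[1], atrisk),
                       flag = flag,
                       stringsAsFactors = FALSE),
            class = c("risk_curve", "data.frame"))
}

# Truncate a curve (set NA + flag) from the first year with an empty
# weighted risk set while events could still occur.
truncate_empty <- function(risk, den, flag) {
  empty <- which(den <= 0)
  if (length(empty)) {
    cut <- empty[1]
    risk[cut:length(risk)] <- NA_real_
    flag[(cut + 1):length(flag)] <- "empty risk set"
  }
  list(risk = risk, flag = flag)
}

#' Weighted yearly hazard series
#'
#' Cause-specific dementia hazard, death-before-dementia hazard (both over
#' the alive-and-dementia-free risk set) and all-cause death hazard (over
#' the alive risk set, post-dementia years included), weighted.  Rows where
#' dementia and death fall in the same year count as dementia events in
#' `h_y` and as deaths in `h_d_all`, but not in `h_d` (death before
#' dementia), matching the dementia-first within-year convention.
#'
#' @param py a person-year table from [expand_person_years()].
#' @param weights `NULL` (unit), an `iptw` object, a `weight_set`, or a
#'   numeric vector per `py` row.
#' @param arm restrict to one exposure arm (0/1), or `NULL` for all rows.
#' @return data frame with one row per year: `h_y, h_d, h_d_all`, and the
#'   weighted risk-set sizes `n_dem_riskset`, `n_alive_riskset`.
#' @export
hazard_series <- function(py, weights = NULL, arm = NULL) {
  w <- resolve_weights(weights, py)
  K <- attr(py, "horizon") %||% max(py$year)
  year <- py$year; y <- py$y; d <- py$d
  atrisk <- py$at_risk_dementia == 1
  if (!is.null(arm)) {
    keep <- py$a == arm
    year <- year[keep]; y <- y[keep]; d <- d[keep]
    atrisk <- atrisk[keep]; w <- w[keep]
  }
  s_dem <- year_sums(year[atrisk], w[atrisk],
                     list(y = y[atrisk], d_pre = d[atrisk] * (1 - y[atrisk])), K)
  s_all <- year_sums(year, w, list(d = d), K)
  rate <- function(num, den) ifelse(den > 0, num / den, 0)
  data.frame(year = seq_len(K),
             h_y = rate(s_dem$y, s_dem$den),
             h_d = rate(s_dem$d_pre, s_dem$den),
             h_d_all = rate(s_all$d, s_all$den),
             n_dem_riskset = s_dem$den,
             n_alive_riskset = s_all$den)
}

#' Cause-specific cumulative incidence of dementia (Aalen-Johansen)
#'
#' The "crude risk" targeted by the total effect: subjects who die before
#' dementia stay in the denominator and never enter the numerator.  In
#' discrete time, `R(t) = sum_{j<=t} S(j-1) h_y(j)` with
#' `S(j) = prod_{m<=j}(1 - h_y(m) - h_d(m))`, hazards weighted over the
#' alive-and-dementia-free risk set.  Weights should carry no censoring
#' component (treatment weights only).
#'
#' @inheritParams hazard_series
#' @return a `risk_curve` data frame (year 0..K; `risk(0) = 0`); the curve
#'   is truncated with a flag if the weighted risk set empties mid
#'   follow-up.
#' @examples
#' coh <- simulate_cohort(dgp_config(n = 1000, seed = 5))
#' py <- expand_person_years(coh)
#' cause_specific_risk(py, arm = 1)[21, ]
#' @export
cause_specific_risk <- function(py, weights = NULL, arm = NULL) {
  h <- hazard_series(py, weights, arm)
  K <- nrow(h)
  S <- cumprod(1 - h$h_y - h$h_d)
  risk <- cumsum(c(1, S[-K]) * h$h_y)
  tr <- truncate_empty(risk, h$n_dem_riskset, rep("", K + 1))
  new_risk_curve("total_effect_dementia", arm %||% NA, tr$risk,
                 h$n_dem_riskset, K, tr$flag)
}

#' Net risk of dementia under elimination of death (weighted Kaplan-Meier)
#'
#' The "marginal cumulative incidence" targeted by the controlled direct
#' effect: the complement of a Kaplan-Meier survival estimator in which
#' death acts as censoring, weighted by the product of treatment and
#' time-varying censoring-by-death weights, `R(t) = 1 - prod_{j<=t}
#' (1 - h_y(j))`.  Subjects dead by year t carry weight zero and so exit
#' the weighted risk set.
#'
#' @inheritParams hazard_series
#' @param weights a `weight_set` combining treatment and censoring
#'   components (see [combine_weights()]); unit weights reduce the
#'   estimator to the unweighted KM complement.
#' @return a `risk_curve` data frame; warns when a year's weighted risk set
#'   falls below 1\% of its baseline size (positivity erosion).
#' @export
net_risk <- function(py, weights = NULL, arm = NULL) {
  h <- hazard_series(py, weights, arm)
  K <- nrow(h)
  risk <- 1 - cumprod(1 - h$h_y)
  if (any(h$n_dem_riskset > 0) &&
      any(h$n_dem_riskset < 0.01 * h$n_dem_riskset[1] & h$n_dem_riskset > 0))
    warning("weighted risk set below 1% of baseline (positivity erosion)",
            call. = FALSE)
  tr <- truncate_empty(risk, h$n_dem_riskset, rep("", K + 1))
  new_risk_curve("cde_dementia", arm %||% NA, tr$risk, h$n_dem_riskset, K,
                 tr$flag)
}

#' All-cause mortality risk (Kaplan-Meier complement)
#'
#' Risk of death from any cause by each year, with time to death retained
#' beyond a dementia diagnosis: the risk set at year t is everyone alive
#' through t-1, including subjects already diagnosed.  Weighted by
#' treatment weights only.
#'
#' @inheritParams hazard_series
#' @return a `risk_curve` data frame.
#' @export
mortality_risk <- function(py, weights = NULL, arm = NULL) {
  h <- hazard_series(py, weights, arm)
  K <- nrow(h)
  risk <- 1 - cumprod(1 - h$h_d_all)
  tr <- truncate_empty(risk, h$n_alive_riskset, rep("", K + 1))
  new_risk_curve("mortality", arm %||% NA, tr$risk, h$n_alive_riskset, K,
                 tr$flag)
}

#' Cumulative incidence of death before dementia
#'
#' The competing-event counterpart of [cause_specific_risk()], computed
#' symmetrically (`sum S(j-1) h_d(j)`).  Together with the dementia risk
#' and the event-free survival it partitions probability one at every year
#' under common weights.
#'
#' @inheritParams hazard_series
#' @return a `risk_curve` data frame.
#' @export
death_before_dementia_risk <- function(py, weights = NULL, arm = NULL) {
  h <- hazard_series(py, weights, arm)
  K <- nrow(h)
  S <- cumprod(1 - h$h_y - h$h_d)
  risk <- cumsum(c(1, S[-K]) * h$h_d)
  tr <- truncate_empty(risk, h$n_dem_riskset, rep("", K + 1))
  new_risk_curve("death_before_dementia", arm %||% NA, tr$risk,
                 h$n_dem_riskset, K, tr$flag)
}

#' @export
print.risk_curve <- function(x, ...) {
  K <- max(x$year)
  cat(sprintf("Risk curve: %s, arm = %s, horizon = %d years\n",
              x$estimand[1], format(x$arm[1]), K))
  show <- x[x$year %in% unique(c(0, 1, 2, 5, 10, 15, K)), ]
  print(data.frame(year = show$year, risk = signif(show$risk, 4),
                   atrisk_w = signif(show$atrisk_w, 5)), row.names = FALSE)
  if (any(nzchar(x$flag))) cat("flags:", unique(x$flag[nzchar(x$flag)]), "\n")
  invisible(x)
}

#' @export
plot.risk_curve <- function(x, add = FALSE, col = 1, lty = 1, ...) {
  if (!add)
    graphics::plot(x$year, x$risk, type = "s", xlab = "Years of follow-up",
                   ylab = "Risk", ylim = c(0, max(x$risk, na.rm = TRUE) * 1.1),
                   col = col, lty = lty, ...)
  else graphics::lines(x$year, x$risk, type = "s", col = col, lty = lty, ...)
  invisible(x)
}
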