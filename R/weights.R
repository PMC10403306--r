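#' Inverse-probability-of-treatment weights
#'
#' Fits a logistic model for the exposure on baseline confounders and
#' returns per-subject weights `1 / P(A = a_i | L_i)` (the inverse of the
#' probability of quitting for quitters and of continuing for continuing
#' smokers).  With `stabilized = TRUE` the numerator is the marginal
#' exposure frequency.
#'
#' @param cohort a cohort data frame (see [validate_cohort()]).
#' @param covariates baseline confounder columns entering the model
#'   linearly.
#' @param stabilized use marginal-probability numerators.
#' @param floor fitted probabilities below this raise a positivity warning
#'   naming the offending subjects.
#' @return an object of class `iptw` with elements `w` (per-subject weight,
#'   aligned to cohort rows), `p` (fitted probability of the received
#'   exposure), `fit` (coefficients, convergence), and the model specification used.
#' @examples
#' coh <- simulate_cohort(dgp_config(n = 2000, seed = 4))
#' tw <- fit_treatment_weights(coh)
#' mean(tw$w)  # ~ 2 under a well-specified model (two exposure levels)
#' @export
fit_treatment_weights <- function(cohort,
                                  covariates = c("age0", "sex", "apoe4", "education"),
                                  stabilized = FALSE, floor = 1e-8) {
  a <- cohort$a
  if (length(unique(a)) < 2)
    stop("both exposure levels must be present to fit treatment weights")
  covariates <- intersect(covariates, names(cohort))
  x <- cbind("(Intercept)" = 1, as.matrix(cohort[covariates]))
  fit <- fit_logit(x, a, context = "treatment model")
  p1 <- stats::plogis(drop(x %*% fit$coef))
  p_received <- ifelse(a == 1, p1, 1 - p1)
  low <- p_received < floor
  if (any(low))
    warning("positivity: fitted exposure probability below ", floor,
            " for subject(s) ",
            paste(utils::head(cohort$subject_id[low], 5), collapse = ", "),
            call. = FALSE)
  num <- if (stabilized) ifelse(a == 1, mean(a), 1 - mean(a)) else 1
  structure(list(w = num / pmax(p_received, floor), p = p_received,
                 fit = fit, covariates = covariates,
                 stabilized = stabilized),
            class = "iptw")
}

# Design matrix for the pooled logistic death-hazard model.
ipcw_design <- function(py, baseline, timevarying, time_terms, K) {
  tt <- switch(time_terms,
    quadratic = cbind(year = py$year, year2 = py$year^2),
    indicators = {
      m <- outer(py$year, seq_len(K)[-1], `==`) * 1
      colnames(m) <- paste0("year", seq_len(K)[-1])
      m
    },
    stop("unknown time_terms: ", time_terms))
  cols <- intersect(c(baseline, timevarying), names(py))
  x <- cbind("(Intercept)" = 1, tt,
             if (length(cols)) as.matrix(py[cols]))
  x
}

#' Inverse-probability-of-censoring-by-death weights
#'
#' Fits a pooled (person-year) logistic model for death among subjects
#' alive and dementia-free at the start of each year, and forms the
#' time-varying censoring weight
#' `w_C(t) = prod_{j <= t} 1 / P(D_j = 0 | D_{j-1} = 0, Y_{j-1} = 0, A, L_j)`.
#' A subject dead by year t has `w_C(t) = 0`.  These weights make the
#' weighted Kaplan-Meier complement target the dementia risk in the
#' hypothetical world where death is eliminated, under exchangeability for
#' censoring-by-death given the modelled covariates.
#'
#' @param py a person-year table from [expand_person_years()].
#' @param baseline baseline covariate columns (includes the exposure by
#'   default, per the censoring-exchangeability reasoning).
#' @param timevarying time-varying covariate columns measured at the start
#'   of each year.  Use `baseline = NULL, timevarying = NULL` for the
#'   unconditional (intercept + time only) tier.
#' @param time_terms `"quadratic"` (year + year^2, the default) or
#'   `"indicators"` (a dummy per year; saturated in time, can be unstable in
#'   small fixtures).
#' @param floor fitted yearly survival probabilities below this raise a
#'   positivity warning.
#' @return an object of class `ipcw` with elements `w_c` (cumulative weight
#'   aligned to `py` rows; `NA` on post-dementia rows where it is never
#'   used), `p_surv` (fitted yearly survival), `fit`, and the model specification used.
#' @export
fit_censoring_weights <- function(py,
                                  baseline = c("a", "age0", "sex", "apoe4", "education"),
                                  timevarying = c("sbp", "bmi", "comorb"),
                                  time_terms = c("quadratic", "indicators"),
                                  floor = 1e-8) {
  time_terms <- match.arg(time_terms)
  K <- attr(py, "horizon") %||% max(py$year)
  sel <- py$at_risk_dementia == 1
  x <- ipcw_design(py[sel, , drop = FALSE], baseline, timevarying, time_terms, K)
  fit <- fit_logit(x, py$d[sel], context = "censoring (death-hazard) model")
  p_surv <- 1 - stats::plogis(drop(x %*% fit$coef))
  if (any(p_surv < floor))
    warning("positivity: fitted yearly survival below ", floor,
            " in the censoring model", call. = FALSE)
  # at-risk segments always run year 1..min(dementia, death, K), contiguously
  first <- py$year[sel] == 1L
  w <- segment_cumprod(1 / pmax(p_surv, floor), first)
  w[py$d[sel] == 1] <- 0        # dead by t => year-t censoring weight is zero
  w_c <- rep(NA_real_, nrow(py))
  w_c[sel] <- w
  structure(list(w_c = w_c, p_surv = p_surv, fit = fit,
                 baseline = baseline, timevarying = timevarying,
                 time_terms = time_terms),
            class = "ipcw")
}

#' Combine treatment and censoring weights
#'
#' Forms the per-person-year combined weight `w(t) = w_A x w_C(t)` used by
#' the controlled-direct-effect estimator.  Either component may be `NULL`
#' (treated as all-ones), so the combination is the identity when only one
#' component is supplied.
#'
#' @param treatment an `iptw` object from [fit_treatment_weights()], or
#'   `NULL`.
#' @param censoring an `ipcw` object from [fit_censoring_weights()], or
#'   `NULL`.
#' @param py the person-year table both components refer to.
#' @return an object of class `weight_set` with elements `w` (combined, per
#'   `py` row), `w_a` (treatment component per row), `w_c` (censoring
#'   component per row).
#' @export
combine_weights <- function(treatment = NULL, censoring = NULL, py) {
  w_a <- if (is.null(treatment)) rep(1, nrow(py)) else treatment$w[py$.subj_row]
  w_c <- if (is.null(censoring)) rep(1, nrow(py)) else censoring$w_c
  structure(list(w = w_a * w_c, w_a = w_a, w_c = w_c,
                 treatment = treatment, censoring = censoring),
            class = "weight_set")
}

#' Weight diagnostics and optional truncation
#'
#' Summary statistics (mean, SD, range, percentiles) and the effective
#' sample size `(sum w)^2 / sum w^2` of a weight vector, with optional
#' truncation at an upper percentile.  Diagnostics are computed before and
#' after truncation; zeros (post-death censoring weights) are excluded from
#' percentile capping but kept in the summaries.
#'
#' @param w a numeric weight vector, or a `weight_set` (its combined `w`).
#' @param truncation_percentile cap weights at this percentile (e.g. 99);
#'   `NULL` or 100 leaves them untouched.
#' @return a list of class `weight_diagnostics`: `before`, `after` (stat
#'   tables), `n_capped`, and `w` (the possibly truncated vector).
#' @export
diagnose_weights <- function(w, truncation_percentile = NULL) {
  if (inherits(w, "weight_set")) w <- w$w
  w <- w[!is.na(w)]
  stat <- function(v) {
    q <- stats::quantile(v, c(.01, .25, .5, .75, .99), names = FALSE)
    data.frame(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v),
               p01 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p99 = q[5],
               ess = if (any(v > 0)) sum(v)^2 / sum(v^2) else 0)
  }
  before <- stat(w)
  n_capped <- 0L
  out_w <- w
  if (!is.null(truncation_percentile) && truncation_percentile < 100) {
    pos <- w > 0
    cap <- stats::quantile(w[pos], truncation_percentile / 100, names = FALSE)
    n_capped <- sum(w > cap)
    out_w <- pmin(w, cap)
  }
  structure(list(before = before, after = stat(out_w),
                 n_capped = n_capped, w = out_w),
            class = "weight_diagnostics")
}

#' @export
print.weight_diagnostics <- function(x, ...) {
  cat("Weight diagnostics (before truncation):\n")
  print(round(x$before, 3), row.names = FALSE)
  if (x$n_capped > 0) {
    cat(sprintf("Truncation capped %d weight(s); after:\n", x$n_capped))
    print(round(x$after, 3), row.names = FALSE)
  }
  invisible(x)
}
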