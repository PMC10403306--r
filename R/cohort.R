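#' Cohort data model
#'
#' A cohort is a plain data frame with one row per subject:
#' \describe{
#'   \item{subject_id}{identifier (character or integer, unique)}
#'   \item{a}{baseline point exposure, 1 = quit smoking, 0 = continue}
#'   \item{age0, sex, apoe4, education}{baseline covariates: age in years,
#'     sex indicator (1 = female), APOE-e4 carrier indicator, education
#'     level coded 1--4}
#'   \item{sbp_1..sbp_K, bmi_1..bmi_K, comorb_1..comorb_K}{optional
#'     time-varying covariates measured at the start of each follow-up year:
#'     systolic blood pressure (mm Hg), body-mass index (kg/m2), and a
#'     comorbidity indicator (heart disease, cancer, stroke or diabetes)}
#'   \item{dementia_year}{year of dementia diagnosis in 1..admin_end, NA if none}
#'   \item{death_year}{year of death in 1..admin_end, NA if none}
#'   \item{admin_end}{administrative end of follow-up in years (K)}
#' }
#' Dementia cannot be recorded after death (`dementia_year <= death_year`);
#' death after a dementia diagnosis is allowed (semicompeting structure).
#'
#' @param cohort a cohort data frame.
#' @param horizon follow-up horizon in years; defaults to `max(admin_end)`.
#' @return `validate_cohort()` returns the cohort invisibly, or stops with a
#'   message naming the offending subjects.
#' @examples
#' coh <- simulate_cohort(dgp_config(n = 50, seed = 1))
#' validate_cohort(coh)
#' @export
validate_cohort <- function(cohort, horizon = NULL) {
  required <- c("subject_id", "a", "dementia_year", "death_year", "admin_end")
  miss <- setdiff(required, names(cohort))
  if (length(miss))
    stop("cohort is missing required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$subject_id))
    stop("duplicate subject_id values")
  if (!all(cohort$a %in% c(0, 1)))
    stop("exposure 'a' must be 0/1")
  K <- horizon %||% max(cohort$admin_end)
  bad <- function(y) !is.na(y) & (y < 1 | y > cohort$admin_end | y != floor(y))
  for (col in c("dementia_year", "death_year")) {
    b <- bad(cohort[[col]])
    if (any(b))
      stop(col, " outside 1..admin_end for subject(s): ",
           paste(utils::head(cohort$subject_id[b], 5), collapse = ", "))
  }
  b <- !is.na(cohort$dementia_year) & !is.na(cohort$death_year) &
    cohort$dementia_year > cohort$death_year
  if (any(b))
    stop("dementia_year after death_year (invalid record) for subject(s): ",
         paste(utils::head(cohort$subject_id[b], 5), collapse = ", "))
  invisible(cohort)
}

# Last-observation-carried-forward across the columns of a subject x year
# matrix; a missing first-year value is an error (no value to carry).
locf_matrix <- function(m, label) {
  if (!anyNA(m)) return(m)
  if (anyNA(m[, 1]))
    stop("missing ", label, " at year 1 cannot be carried forward")
  for (j in 2:ncol(m)) {
    na <- is.na(m[, j])
    if (any(na)) m[na, j] <- m[na, j - 1]
  }
  m
}

tv_matrix <- function(cohort, prefix, K) {
  cols <- paste0(prefix, "_", seq_len(K))
  if (!all(cols %in% names(cohort))) return(NULL)
  locf_matrix(as.matrix(cohort[cols]), prefix)
}

#' Expand a wide cohort to a person-year table
#'
#' One row per subject-year while the subject is alive: rows run from year 1
#' to `min(death_year, horizon)`.  `at_risk_dementia` flags years in which
#' the subject is alive and dementia-free at the year's start (the risk set
#' for the dementia hazard); `at_risk_death` flags years alive at the start
#' regardless of dementia status, so mortality follow-up continues past a
#' dementia diagnosis.  When dementia and death fall in the same year the
#' dementia event is recorded first: `y` and `d` may both be 1 on one row.
#'
#' @inheritParams validate_cohort
#' @param timevarying prefixes of time-varying covariate column blocks to
#'   carry into the long table (skipped when absent from the cohort).
#' @return data frame with columns `subject_id, year, at_risk_dementia,
#'   at_risk_death, y, d, a`, baseline covariates, any time-varying
#'   covariates evaluated at the start of the year, and `.subj_row`, the row
#'   index of the subject in `cohort`.  The horizon is attached as
#'   `attr(, "horizon")`.
#' @examples
#' coh <- simulate_cohort(dgp_config(n = 20, seed = 2))
#' py <- expand_person_years(coh)
#' head(py)
#' @export
expand_person_years <- function(cohort, horizon = NULL,
                                timevarying = c("sbp", "bmi", "comorb")) {
  validate_cohort(cohort, horizon)
  K <- horizon %||% max(cohort$admin_end)
  if (K < 1) stop("horizon must be >= 1")
  dem <- cohort$dementia_year
  dth <- cohort$death_year
  if (any(!is.na(dem) & dem > K) || any(!is.na(dth) & dth > K))
    stop("event years exceed the requested horizon")
  stop_year <- pmin(ifelse(is.na(dth), K, dth), pmin(cohort$admin_end, K))
  idx <- rep.int(seq_len(nrow(cohort)), stop_year)
  year <- sequence(stop_year)
  out <- list(
    subject_id = cohort$subject_id[idx],
    year = year,
    at_risk_dementia = as.integer(is.na(dem[idx]) | year <= dem[idx]),
    at_risk_death = rep(1L, length(idx)),
    y = as.integer(!is.na(dem[idx]) & year == dem[idx]),
    d = as.integer(!is.na(dth[idx]) & year == dth[idx]),
    a = cohort$a[idx]
  )
  for (col in intersect(c("age0", "sex", "apoe4", "education"), names(cohort)))
    out[[col]] <- cohort[[col]][idx]
  for (pre in timevarying) {
    m <- tv_matrix(cohort, pre, K)
    if (!is.null(m)) out[[pre]] <- m[cbind(idx, year)]
  }
  out$.subj_row <- idx
  out <- structure(out, class = "data.frame",
                   row.names = c(NA_integer_, -length(idx)))
  attr(out, "horizon") <- K
  out
}

#' Read / write a wide cohort CSV
#'
#' Comma-delimited UTF-8 with a header row; one row per subject with
#' time-varying covariates as suffixed columns (`sbp_1 .. sbp_K`).  Numeric
#' fields are written with full precision so that write-then-read is an
#' exact round trip.  On read, missing time-varying values are carried
#' forward from the last observed year; unknown columns are kept with a
#' warning; malformed rows are reported with their line numbers.
#'
#' @param path file path.
#' @return `read_cohort()` returns a validated cohort data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "a", "dementia_year", "death_year", "admin_end")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("cohort file is missing required columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(df)
  known <- c(required, "age0", "sex", "apoe4", "education", "dropout_year")
  tv <- grepl("^(sbp|bmi|comorb)_[0-9]+$", names(df))
  unknown <- setdiff(names(df)[!tv], known)
  if (length(unknown))
    warning("unknown columns kept as-is: ", paste(unknown, collapse = ", "))
  malformed <- is.na(df$a) | is.na(df$admin_end)
  if (any(malformed))
    stop("malformed rows (missing exposure or admin_end) at line(s): ",
         paste(which(malformed) + 1L, collapse = ", "))
  # store all numeric fields as double so write-then-read is type-stable
  for (col in setdiff(names(df), "subject_id"))
    if (is.numeric(df[[col]]) || all(is.na(df[[col]])))
      df[[col]] <- as.numeric(df[[col]])
  K <- max(df$admin_end)
  for (pre in c("sbp", "bmi", "comorb")) {
    cols <- paste0(pre, "_", seq_len(K))
    if (all(cols %in% names(df)))
      df[cols] <- locf_matrix(as.matrix(df[cols]), pre)
  }
  # optional dropout shortens that subject's administrative follow-up
  if ("dropout_year" %in% names(df)) {
    has <- !is.na(df$dropout_year)
    df$admin_end[has] <- pmin(df$admin_end[has], df$dropout_year[has])
  }
  validate_cohort(df)
  df
}

#' @rdname read_cohort
#' @inheritParams validate_cohort
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      s <- sprintf("%.17g", out[[j]])
      s[is.na(out[[j]])] <- NA
      out[[j]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Crude per-arm event counts and proportions
#'
#' Counts and percentages (one decimal) of subjects with dementia and with
#' death by year `horizon`, per exposure arm and overall -- the descriptive
#' table an emulated-trial report opens with.
#'
#' @inheritParams validate_cohort
#' @return data frame with rows `continue`, `quit`, `overall` and columns
#'   `n, dementia, dementia_pct, death, death_pct, flag` (`flag` marks an
#'   empty arm, whose percentages are undefined).
#' @examples
#' crude_summary(simulate_cohort(dgp_config(n = 500, seed = 3)))
#' @export
crude_summary <- function(cohort, horizon = NULL) {
  validate_cohort(cohort, horizon)
  K <- horizon %||% max(cohort$admin_end)
  one <- function(sub) {
    n <- nrow(sub)
    dem <- sum(!is.na(sub$dementia_year) & sub$dementia_year <= K)
    dth <- sum(!is.na(sub$death_year) & sub$death_year <= K)
    data.frame(n = n, dementia = dem,
               dementia_pct = if (n > 0) round1(100 * dem / n) else NA_real_,
               death = dth,
               death_pct = if (n > 0) round1(100 * dth / n) else NA_real_,
               flag = if (n == 0) "empty arm" else "")
  }
  out <- rbind(one(cohort[cohort$a == 0, , drop = FALSE]),
               one(cohort[cohort$a == 1, , drop = FALSE]),
               one(cohort))
  rownames(out) <- NULL
  out <- cbind(arm = c("continue", "quit", "overall"), out)
  attr(out, "horizon") <- K
  out
}
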