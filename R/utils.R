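# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed for the duration of `code` and restores the caller's
#' `.Random.seed` afterwards, so simulation functions do not disturb the
#' global stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Logistic fit on a prebuilt design matrix.  glm.fit() is used directly
# because bootstrap replicates and pooled person-year fits make the
# model.frame machinery of glm() the dominant cost.
fit_logit <- function(x, y, context = "logistic model") {
  # tight IRLS tolerance: saturated-model identities are asserted to ~1e-8
  fit <- suppressWarnings(stats::glm.fit(x, y, family = stats::binomial(),
                                         control = list(epsilon = 1e-12,
                                                        maxit = 100)))
  if (!fit$converged)
    warning(context, " did not converge", call. = FALSE)
  p <- fit$fitted.values
  if (any(p < 1e-12) || any(p > 1 - 1e-12) || any(abs(fit$coefficients) > 20, na.rm = TRUE))
    warning(context, ": fitted probabilities at or near 0/1 (possible separation)",
            call. = FALSE)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0  # aliased columns drop out of the linear predictor
  list(coef = coefs, converged = fit$converged)
}

# Per-group cumulative product over contiguous group segments (rows must be
# grouped; used for the telescoping censoring weights).
segment_cumprod <- function(x, first) {
  lx <- log(x)
  cs <- cumsum(lx)
  gid <- cumsum(first)
  base <- (cs - lx)[first]          # cumulative log-product before each segment
  exp(cs - base[gid])
}

round1 <- function(x) round(x + 1e-9, 1)  # guard half-even against FP dust
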