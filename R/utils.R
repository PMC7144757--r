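# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) stats::plogis(x)

#' @noRd
#' Deterministic 31-bit seed for a named substream of a master seed.
#' Each logical draw (covariates, assignment, outcomes, ...) gets its own
#' stream so adding one draw never perturbs another.
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647L
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(stream_seed(seed, name))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
#' Maximum-likelihood logistic regression on a prebuilt design matrix.
#'
#' Thin wrapper around stats::glm.fit with a tight convergence tolerance.
#' Rank-deficient designs are handled by dropping aliased columns (their
#' coefficients are reported as 0 and `aliased` records which); a constant
#' response short-circuits to a degenerate fit predicting that constant.
#' Suspected separation (unconverged IRLS or runaway coefficients) is an
#' error naming the offending columns.
fit_logistic <- function(x, y, what = "model") {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (length(unique(y)) == 1L) {
    return(list(coefficients = NULL, constant = y[1], aliased = character(0),
                columns = colnames(x)))
  }
  qx <- qr(x)
  keep <- sort(qx$pivot[seq_len(qx$rank)])
  xr <- x[, keep, drop = FALSE]
  fit <- suppressWarnings(stats::glm.fit(
    xr, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 200)
  ))
  beta <- fit$coefficients
  if (!fit$converged || any(!is.finite(beta))) {
    stopf("logistic fit for %s failed to converge (possible separation in: %s)",
          what, paste(colnames(xr)[!is.finite(beta) | abs(beta) > 15],
                      collapse = ", "))
  }
  if (any(abs(beta) > 25)) {
    stopf("logistic fit for %s shows signs of separation in: %s",
          what, paste(colnames(xr)[abs(beta) > 25], collapse = ", "))
  }
  full <- setNames(numeric(ncol(x)), colnames(x))
  full[keep] <- beta
  list(coefficients = full, constant = NULL,
       aliased = setdiff(colnames(x), colnames(x)[keep]), columns = colnames(x))
}

predict_logistic <- function(fit, x) {
  if (!is.null(fit$constant)) return(rep(fit$constant, nrow(x)))
  inv_logit(drop(x[, names(fit$coefficients), drop = FALSE] %*%
                   fit$coefficients))
}

#' @noRd
#' Check a cohort data frame against the package's column contract.
validate_cohort <- function(cohort, covariates = NULL, require_treatment = TRUE) {
  need <- c("id", "outcome", "event_offset_days")
  if (require_treatment) need <- c(need, "treatment", "treatment_start_offset_days")
  miss <- setdiff(c(need, covariates), names(cohort))
  if (length(miss)) {
    stopf("cohort is missing required column(s): %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(cohort$id)) stopf("cohort ids must be unique")
  if (!all(cohort$outcome %in% c(0, 1))) stopf("outcome must be 0/1")
  bad <- cohort$outcome == 1 & (is.na(cohort$event_offset_days) |
                                  cohort$event_offset_days < 0)
  if (any(bad)) stopf("subjects with an event need a non-negative event offset")
  invisible(cohort)
}
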