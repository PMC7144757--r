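# The fixed prognostic model and the predictiveness curve.
#
# The decision rule is built on top of a prognostic risk model that is
# treated as fixed once chosen: either fitted here on a training partition
# or supplied externally (coefficients from a published model). The
# predictiveness curve summarises the distribution of predicted risk and is
# the device used to choose the high/low-risk cutoff.

#' Fit the prognostic risk model
#'
#' Maximum-likelihood logistic regression of the binary outcome on baseline
#' covariates (main effects). The fitted model is the "fixed prognostic
#' model" of the workflow; downstream stages treat its coefficients as
#' frozen.
#'
#' @param cohort cohort data frame (see [simulate_cohort()] for the schema).
#' @param covariates character vector of covariate column names; may be
#'   empty for an intercept-only model.
#' @return an object of class `risk_model` with elements `covariates`,
#'   `coefficients` (intercept first) and `provenance`.
#' @export
fit_risk_model <- function(cohort, covariates) {
  validate_cohort(cohort, covariates, require_treatment = FALSE)
  y <- cohort$outcome
  if (length(unique(y)) < 2L) {
    stopf("risk model needs both an event and a non-event in the data")
  }
  x <- cbind(`(Intercept)` = 1,
             as.matrix(cohort[, covariates, drop = FALSE]))
  fit <- fit_logistic(x, y, what = "risk model")
  if (length(fit$aliased)) {
    stopf("risk model design is rank deficient; offending covariate(s): %s",
          paste(fit$aliased, collapse = ", "))
  }
  risk_model(covariates, fit$coefficients, provenance = "fitted-internally")
}

#' Construct a risk model from known coefficients
#'
#' Used when the prognostic model is external information (e.g. a published
#' model) rather than fitted on a training partition.
#'
#' @param covariates ordered character vector of covariate names.
#' @param coefficients numeric vector, intercept first, on the log-odds
#'   scale.
#' @param provenance `"fitted-internally"` or `"supplied-externally"`.
#' @return an object of class `risk_model`.
#' @export
risk_model <- function(covariates, coefficients,
                       provenance = c("supplied-externally", "fitted-internally")) {
  provenance <- match.arg(provenance)
  if (length(coefficients) != length(covariates) + 1L) {
    stopf("coefficients must have length 1 + number of covariates")
  }
  names(coefficients) <- c("(Intercept)", covariates)
  structure(list(covariates = covariates, coefficients = coefficients,
                 provenance = provenance),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Prognostic risk model (logistic, %s)\n", x$provenance))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) object$coefficients

#' Predicted event risk for each subject
#'
#' @param object a `risk_model`.
#' @param newdata cohort data frame containing every model covariate.
#' @param ... unused.
#' @return numeric vector of predicted risks in (0, 1), one per row.
#' @export
predict.risk_model <- function(object, newdata, ...) {
  miss <- setdiff(object$covariates, names(newdata))
  if (length(miss)) {
    stopf("cohort lacks risk-model covariate column(s): %s",
          paste(miss, collapse = ", "))
  }
  x <- cbind(1, as.matrix(newdata[, object$covariates, drop = FALSE]))
  inv_logit(drop(x %*% object$coefficients))
}

#' @rdname predict.risk_model
#' @param model a `risk_model`.
#' @param cohort cohort data frame.
#' @export
predict_risk <- function(model, cohort) predict(model, cohort)

#' Serialize a risk model to a flat key-value text file
#'
#' @param model a `risk_model`.
#' @param path file path.
#' @export
write_risk_model <- function(model, path) {
  yaml::write_yaml(list(covariates = as.list(model$covariates),
                        coefficients = as.list(unname(model$coefficients)),
                        provenance = model$provenance),
                   path)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  d <- yaml::read_yaml(path)
  risk_model(as.character(unlist(d$covariates)),
             as.numeric(unlist(d$coefficients)),
             provenance = d$provenance %||% "supplied-externally")
}

#' Predictiveness curve of a risk score
#'
#' For each grid point `p` the curve reports the empirical `p`-quantile of
#' the predicted risks (`risk_at_quantile`, the classical predictiveness
#' curve R(p)) and, as a companion diagnostic, the observed event rate among
#' subjects whose risk exceeds that quantile (`outcome_rate_above`). A
#' well-calibrated, useful risk score has a steep curve: low risk for most
#' of the population and high observed event rates above the upper
#' quantiles.
#'
#' Quantiles use the standard interpolating empirical quantile
#' (`stats::quantile`, type 7); the convention is fixed package-wide so
#' cutoffs chosen from the curve are reproducible.
#'
#' @param risks numeric vector of predicted risks.
#' @param outcomes 0/1 outcome vector aligned with `risks`.
#' @param quantile_grid strictly increasing grid in `[0, 1]`.
#' @return object of class `predictiveness_curve`: a data frame with columns
#'   `quantile`, `risk_at_quantile`, `outcome_rate_above` (NA where no
#'   subject lies above the quantile).
#' @export
predictiveness_curve <- function(risks, outcomes,
                                 quantile_grid = seq(0.05, 0.95, by = 0.05)) {
  if (length(risks) != length(outcomes)) {
    stopf("risks (%d) and outcomes (%d) are not aligned",
          length(risks), length(outcomes))
  }
  if (!all(outcomes %in% c(0, 1))) stopf("outcomes must be 0/1")
  if (is.unsorted(quantile_grid, strictly = TRUE) ||
      any(quantile_grid < 0 | quantile_grid > 1)) {
    stopf("quantile_grid must be strictly increasing within [0, 1]")
  }
  rq <- unname(stats::quantile(risks, quantile_grid, type = 7))
  rate <- vapply(rq, function(q) {
    above <- risks > q
    if (!any(above)) NA_real_ else mean(outcomes[above])
  }, numeric(1))
  structure(
    data.frame(quantile = quantile_grid, risk_at_quantile = rq,
               outcome_rate_above = rate),
    class = c("predictiveness_curve", "data.frame"),
    risks = risks, outcomes = outcomes
  )
}

#' @export
print.predictiveness_curve <- function(x, ...) {
  cat(sprintf("Predictiveness curve (%d grid points, n = %d subjects)\n",
              nrow(x), length(attr(x, "risks"))))
  print.data.frame(round(as.data.frame(x), 4), row.names = FALSE)
  invisible(x)
}

#' @export
plot.predictiveness_curve <- function(x, ...) {
  graphics::plot(x$quantile, x$risk_at_quantile, type = "s",
                 xlab = "Risk quantile", ylab = "Predicted risk",
                 ylim = c(0, 1), ...)
  graphics::lines(x$quantile, x$outcome_rate_above, type = "s", lty = 2)
  graphics::legend("topleft", lty = 1:2, bty = "n",
                   legend = c("risk at quantile", "event rate above"))
  invisible(x)
}

#' Choose the high/low-risk cutoff from a predictiveness curve
#'
#' Two criteria are supported: fix the fraction `q` of the population to be
#' labelled high risk (the cutoff is then the `1 - q` risk quantile), or
#' supply an absolute risk threshold, which is returned unchanged.
#'
#' @param curve a [predictiveness_curve()].
#' @param high_risk_fraction target fraction of subjects labelled high risk,
#'   strictly between 0 and 1.
#' @param risk_threshold absolute risk cutoff; returned as-is.
#' @return the cutoff probability.
#' @export
select_cutoff <- function(curve, high_risk_fraction = NULL, risk_threshold = NULL) {
  stopifnot(inherits(curve, "predictiveness_curve"))
  if (is.null(high_risk_fraction) == is.null(risk_threshold)) {
    stopf("supply exactly one of high_risk_fraction or risk_threshold")
  }
  if (!is.null(risk_threshold)) {
    if (risk_threshold < 0 || risk_threshold > 1) {
      stopf("risk_threshold must lie in [0, 1]")
    }
    return(risk_threshold)
  }
  q <- high_risk_fraction
  if (q <= 0 || q >= 1) stopf("high_risk_fraction must lie strictly in (0, 1)")
  unname(stats::quantile(attr(curve, "risks"), 1 - q, type = 7))
}
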