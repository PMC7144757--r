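# Synthetic observational cohorts with known potential outcomes.
#
# The simulator emulates a disease register of newly diagnosed patients in
# which treatment choice depends on baseline covariates (confounding), the
# binary outcome is an adverse event within a fixed horizon (default five
# years), and treatment starts within a short grace period after diagnosis.
# Because both potential outcomes are retained, every estimator in the
# package can be checked against the simulated truth.

#' Simulation configuration for a synthetic observational cohort
#'
#' Describes the data-generating process: baseline covariates, a logistic
#' model for the five-year event risk under the reference treatment, a
#' log-odds treatment effect of `B` versus `A` (optionally interacted with
#' one covariate, which allows qualitative interactions), and a logistic
#' model for the probability of receiving `B` given covariates (the
#' confounding mechanism).
#'
#' @param n_subjects number of subjects to simulate.
#' @param covariates list of covariate specifications, each a list with
#'   `name`, `dist` (one of `"bernoulli"`, `"normal"`, `"uniform"`) and
#'   distribution parameters (`prob`; `mean`/`sd`; `min`/`max`).
#' @param risk_coefficients numeric vector, intercept first then one
#'   coefficient per covariate, on the log-odds scale: the event risk under
#'   treatment `A`.
#' @param treatment_effect log-odds shift applied to the event risk when
#'   treated with `B` instead of `A` (negative means `B` is protective).
#' @param effect_interaction optional named number: an additional log-odds
#'   shift per unit of the named covariate, e.g. `c(x = -2)`.
#' @param confounding_coefficients numeric vector (intercept first) for the
#'   log-odds of receiving `B` given covariates; all zeros gives a
#'   randomized-like cohort with P(B) = 1/2.
#' @param grace_period_days non-negative integer; treatment start offsets
#'   are drawn uniformly on `0:grace_period_days`.
#' @param horizon_days positive integer outcome horizon (default 1826,
#'   i.e. five years).
#' @param treatments two treatment labels, reference first.
#' @param seed integer master seed; each logical draw (each covariate,
#'   assignment, outcomes, timing) uses its own substream derived from it.
#' @return an object of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_subjects,
                       covariates = list(),
                       risk_coefficients,
                       treatment_effect = 0,
                       effect_interaction = NULL,
                       confounding_coefficients,
                       grace_period_days = 14L,
                       horizon_days = 1826L,
                       treatments = c("A", "B"),
                       seed = 1L) {
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  if (grace_period_days < 0 || grace_period_days >= horizon_days) {
    stopf("grace_period_days must be in [0, horizon_days)")
  }
  for (cv in covariates) {
    if (is.null(cv$name) || is.null(cv$dist)) {
      stopf("each covariate spec needs a name and a dist")
    }
    if (!cv$dist %in% c("bernoulli", "normal", "uniform")) {
      stopf("unknown distribution family '%s' for covariate '%s'",
            cv$dist, cv$name)
    }
  }
  p <- length(covariates)
  if (length(risk_coefficients) != p + 1L) {
    stopf("risk_coefficients must have length 1 + number of covariates (%d)",
          p + 1L)
  }
  if (length(confounding_coefficients) != p + 1L) {
    stopf("confounding_coefficients must have length 1 + number of covariates (%d)",
          p + 1L)
  }
  if (!is.null(effect_interaction)) {
    if (is.null(names(effect_interaction)) ||
        !names(effect_interaction) %in% vapply(covariates, `[[`, "", "name")) {
      stopf("effect_interaction must be named after a declared covariate")
    }
  }
  if (length(treatments) != 2L || anyDuplicated(treatments)) {
    stopf("treatments must be two distinct labels")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), covariates = covariates,
         risk_coefficients = risk_coefficients,
         treatment_effect = treatment_effect,
         effect_interaction = effect_interaction,
         confounding_coefficients = confounding_coefficients,
         grace_period_days = as.integer(grace_period_days),
         horizon_days = as.integer(horizon_days),
         treatments = treatments, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d subjects, horizon %d days, grace period %d days\n",
              x$n_subjects, x$horizon_days, x$grace_period_days))
  cat(sprintf("  covariates: %s\n",
              if (length(x$covariates))
                paste(vapply(x$covariates, function(cv)
                  sprintf("%s (%s)", cv$name, cv$dist), ""), collapse = ", ")
              else "(none)"))
  cat(sprintf("  treatment effect (B vs A, log-odds): %g\n", x$treatment_effect))
  if (!is.null(x$effect_interaction)) {
    cat(sprintf("  effect interaction: %+g * %s\n",
                x$effect_interaction, names(x$effect_interaction)))
  }
  invisible(x)
}

#' Simulate an observational cohort with known potential outcomes
#'
#' Draws covariates, assigns treatment from the logistic confounding model,
#' and generates both potential outcomes from the logistic risk model using
#' one shared uniform draw per subject (the subject has the event under a
#' treatment exactly when the draw falls below that treatment's risk), so
#' individual treatment effects are monotone and a zero treatment effect
#' gives identical potential outcomes subject by subject. The observed
#' outcome is the potential outcome under the received treatment
#' (consistency).
#'
#' @param config a [sim_config()] object.
#' @return a list of class `sim_cohort` with components
#'   \describe{
#'     \item{cohort}{data frame: `id`, one column per covariate, `treatment`,
#'       `treatment_start_offset_days`, `outcome`,
#'       `event_offset_days` (`NA` when no event).}
#'     \item{potential}{data frame of simulator-only ground truth:
#'       `y_under_A`, `y_under_B`, `true_risk` (event risk under the
#'       reference treatment `A`).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  X <- matrix(0, n, length(config$covariates))
  cov_names <- vapply(config$covariates, `[[`, "", "name")
  colnames(X) <- cov_names
  for (cv in config$covariates) {
    X[, cv$name] <- with_stream(config$seed, paste0("covariate:", cv$name), {
      switch(cv$dist,
        bernoulli = stats::rbinom(n, 1L, cv$prob %||% 0.5),
        normal    = stats::rnorm(n, cv$mean %||% 0, cv$sd %||% 1),
        uniform   = stats::runif(n, cv$min %||% 0, cv$max %||% 1)
      )
    })
  }
  design <- cbind(1, X)

  lp_risk_A <- drop(design %*% config$risk_coefficients)
  shift <- rep(config$treatment_effect, n)
  if (!is.null(config$effect_interaction)) {
    shift <- shift + config$effect_interaction * X[, names(config$effect_interaction)]
  }
  p_A <- inv_logit(lp_risk_A)
  p_B <- inv_logit(lp_risk_A + shift)

  p_treat_B <- inv_logit(drop(design %*% config$confounding_coefficients))
  trt <- with_stream(config$seed, "assignment", {
    ifelse(stats::runif(n) < p_treat_B, config$treatments[2], config$treatments[1])
  })

  u <- with_stream(config$seed, "outcome", stats::runif(n))
  y_A <- as.integer(u < p_A)
  y_B <- as.integer(u < p_B)
  y <- ifelse(trt == config$treatments[2], y_B, y_A)

  start_off <- with_stream(config$seed, "treatment-start", {
    sample.int(config$grace_period_days + 1L, n, replace = TRUE) - 1L
  })
  ev_off <- with_stream(config$seed, "event-time", {
    ifelse(y == 1L, sample.int(config$horizon_days, n, replace = TRUE), NA_integer_)
  })

  cohort <- data.frame(
    id = sprintf("S%06d", seq_len(n)), X,
    treatment = trt,
    treatment_start_offset_days = start_off,
    outcome = y,
    event_offset_days = as.integer(ev_off),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  potential <- data.frame(y_under_A = y_A, y_under_B = y_B, true_risk = p_A)
  names(potential)[1:2] <- paste0("y_under_", config$treatments)
  structure(list(cohort = cohort, potential = potential, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d subjects, %d covariate(s), event rate %.3f\n",
              nrow(x$cohort), length(x$config$covariates), mean(x$cohort$outcome)))
  invisible(x)
}

#' Exact value of a decision rule from simulated potential outcomes
#'
#' Applies the rule to the supplied risk scores and averages, over subjects,
#' the potential outcome under the treatment the rule assigns. This is the
#' simulation oracle for the rule-arm mean E[Y^pred]: the estimators in
#' [estimate_rule_mean()] and [estimate_delta()] are validated against it.
#'
#' @param sim a `sim_cohort` object (or its `potential` data frame together
#'   with `cohort`).
#' @param rule a [decision_rule()].
#' @param risks numeric vector of risk scores aligned with the cohort rows;
#'   defaults to the simulator's true baseline risk.
#' @return the mean potential outcome under the rule, a number in `[0, 1]`.
#' @export
true_rule_value <- function(sim, rule, risks = sim$potential$true_risk) {
  stopifnot(inherits(sim, "sim_cohort"), inherits(rule, "decision_rule"))
  n <- nrow(sim$cohort)
  if (length(risks) != n) {
    stopf("risks (%d) not aligned with cohort rows (%d)", length(risks), n)
  }
  assigned <- apply_rule(rule, risks)
  cols <- paste0("y_under_", assigned)
  missing_cols <- setdiff(unique(cols), names(sim$potential))
  if (length(missing_cols)) {
    stopf("potential outcomes not available for treatment(s): %s",
          paste(sub("y_under_", "", missing_cols), collapse = ", "))
  }
  y <- sim$potential[cbind(seq_len(n), match(cols, names(sim$potential)))]
  mean(y)
}

#' Write / read a cohort table as delimited text
#'
#' Plain comma-separated text with a header row; missing event offsets are
#' written as empty fields.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @return `read_cohort` returns the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cohort$id <- as.character(cohort$id)
  validate_cohort(cohort)
  cohort
}
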