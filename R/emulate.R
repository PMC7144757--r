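# Emulation of the target trial: rule arm versus standard of care.
#
# The target trial randomizes eligible subjects at diagnosis (time zero) to
# either a prediction-based decision rule or the standard of care, and
# compares the proportion with the adverse event within the horizon. In
# observational data the standard-of-care arm is simply the observed
# eligible population, while the rule arm's mean must be reconstructed by
# per-risk-stratum g-computation: within each stratum, regress the outcome
# on treatment and confounders (the Q model), predict every subject's
# outcome with treatment set to the rule's assignment, and average;
# strata are then combined with their empirical weights.
#
# Grace-period handling: subjects whose event occurs before treatment could
# plausibly have started (event offset <= grace period) are counted, with
# their factual outcome of 1, in BOTH arms regardless of treatment, to
# avoid the survivor bias of conditioning on surviving to treatment start.
# They are excluded from Q-model fitting, where their treatment may be
# undefined.

#' Eligibility and follow-up specification for the emulated trial
#'
#' @param criteria named character vector (or list) of R expressions over
#'   cohort columns, e.g. `c(adult = "age >= 18")`; a subject must satisfy
#'   all of them. Rows evaluating to `NA` are excluded.
#' @param grace_period_days window after time zero within which treatment
#'   may start; events inside it are counted in both arms.
#' @param horizon_days outcome horizon measured from time zero.
#' @return object of class `eligibility_spec`.
#' @export
eligibility_spec <- function(criteria = character(0),
                             grace_period_days = 14L,
                             horizon_days = 1826L) {
  if (grace_period_days < 0 || grace_period_days >= horizon_days) {
    stopf("grace_period_days must be in [0, horizon_days)")
  }
  criteria <- as.list(criteria)
  structure(list(criteria = criteria,
                 grace_period_days = as.integer(grace_period_days),
                 horizon_days = as.integer(horizon_days)),
            class = "eligibility_spec")
}

#' Q-model specification for per-stratum g-computation
#'
#' The Q model is the within-stratum outcome regression
#' E[Y | treatment, covariates]: logistic in a treatment indicator, the
#' named confounders (main effects; continuous confounders enter linearly)
#' and optional treatment-by-covariate interactions. The treatment main
#' effect is always included.
#'
#' @param covariates character vector of confounder column names (may be
#'   empty for a treatment-only model).
#' @param interactions character vector of covariate names whose
#'   interaction with treatment is included.
#' @return object of class `q_model_spec`.
#' @export
q_model_spec <- function(covariates = character(0),
                         interactions = character(0)) {
  bad <- setdiff(interactions, covariates)
  if (length(bad)) {
    stopf("interaction covariate(s) not among the main effects: %s",
          paste(bad, collapse = ", "))
  }
  structure(list(covariates = as.character(covariates),
                 interactions = as.character(interactions)),
            class = "q_model_spec")
}

#' Apply eligibility criteria to a cohort
#'
#' Evaluates each named predicate in the cohort's columns and keeps the rows
#' satisfying all of them; time zero is each subject's diagnosis date, so
#' all offsets are already relative to it. Per-criterion exclusion counts
#' are attached as the `"exclusions"` attribute and reported via `message`.
#'
#' @param cohort cohort data frame.
#' @param spec an [eligibility_spec()].
#' @return the filtered cohort, with an `exclusions` attribute.
#' @export
apply_eligibility <- function(cohort, spec) {
  stopifnot(inherits(spec, "eligibility_spec"))
  validate_cohort(cohort)
  keep <- rep(TRUE, nrow(cohort))
  excl <- integer(0)
  for (k in seq_along(spec$criteria)) {
    expr_txt <- spec$criteria[[k]]
    nm <- names(spec$criteria)[k] %||% expr_txt
    if (is.null(nm) || !nzchar(nm)) nm <- expr_txt
    expr <- str2lang(expr_txt)
    vars <- setdiff(all.vars(expr), names(cohort))
    if (length(vars)) {
      stopf("eligibility criterion '%s' references missing column(s): %s",
            nm, paste(vars, collapse = ", "))
    }
    ok <- eval(expr, cohort, baseenv())
    ok <- !is.na(ok) & ok
    excl[nm] <- sum(keep & !ok)
    keep <- keep & ok
  }
  out <- cohort[keep, , drop = FALSE]
  if (!nrow(out)) warnf("no subject satisfies all eligibility criteria")
  attr(out, "exclusions") <- excl
  out
}

#' Partition an eligible cohort by the grace period
#'
#' Subjects with an event no later than `grace_period_days` after time zero
#' form the early-event set; they are counted in both the rule arm and the
#' standard-of-care arm with their factual outcome and never enter Q-model
#' fits. The boundary is inclusive: an event exactly at the grace-period
#' day is early.
#'
#' @param cohort eligible cohort data frame.
#' @param spec an [eligibility_spec()].
#' @return list with logical vector `early` (aligned with rows), and the
#'   two row-index sets `early_idx`, `main_idx` partitioning the cohort.
#' @export
grace_period_partition <- function(cohort, spec) {
  stopifnot(inherits(spec, "eligibility_spec"))
  off <- cohort$event_offset_days
  if (any(cohort$outcome == 1 & (is.na(off) | off < 0))) {
    stopf("event offsets must be present and non-negative for subjects with events")
  }
  early <- cohort$outcome == 1 & !is.na(off) & off <= spec$grace_period_days
  list(early = early,
       early_idx = which(early),
       main_idx = which(!early))
}

q_design <- function(cohort, q_spec, space, set_treatment = NULL) {
  trt <- if (is.null(set_treatment)) cohort$treatment else
    rep(set_treatment, nrow(cohort))
  tb <- as.numeric(trt == space$treatments[2])
  x <- cbind(`(Intercept)` = 1, treatment = tb)
  if (length(q_spec$covariates)) {
    x <- cbind(x, as.matrix(cohort[, q_spec$covariates, drop = FALSE]))
  }
  for (v in q_spec$interactions) {
    xi <- tb * cohort[[v]]
    colnames_x <- colnames(x)
    x <- cbind(x, xi)
    colnames(x) <- c(colnames_x, paste0("treatment:", v))
  }
  x
}

#' Fit the Q model within a risk stratum
#'
#' Logistic regression of the outcome on a treatment indicator, the
#' specified confounders and any treatment-by-covariate interactions,
#' fitted by maximum likelihood on the supplied subgroup (the stratum's
#' main set: early events excluded, treatments restricted to the action
#' space). A subgroup in which only one treatment was received cannot
#' identify the treatment effect and raises a positivity error; a subgroup
#' with a constant outcome yields a degenerate fit predicting that
#' constant.
#'
#' @param subgroup cohort rows to fit on.
#' @param q_spec a [q_model_spec()].
#' @param space an [action_space()].
#' @param stratum label used in error messages.
#' @return object of class `q_model`.
#' @export
fit_q_model <- function(subgroup, q_spec, space = action_space(),
                        stratum = "stratum") {
  stopifnot(inherits(q_spec, "q_model_spec"))
  miss <- setdiff(q_spec$covariates, names(subgroup))
  if (length(miss)) {
    stopf("Q-model covariate(s) missing from cohort: %s",
          paste(miss, collapse = ", "))
  }
  if (!nrow(subgroup)) stopf("empty subgroup in %s: cannot fit Q model", stratum)
  if (anyNA(subgroup[, q_spec$covariates, drop = FALSE])) {
    stopf("missing covariate values in %s; imputation is out of scope", stratum)
  }
  y <- subgroup$outcome
  if (length(unique(subgroup$treatment)) < 2L && length(unique(y)) > 1L) {
    stopf("positivity failure in %s: every subject received treatment '%s'",
          stratum, subgroup$treatment[1])
  }
  x <- q_design(subgroup, q_spec, space)
  fit <- fit_logistic(x, y, what = sprintf("Q model (%s)", stratum))
  structure(list(fit = fit, q_spec = q_spec, space = space,
                 stratum = stratum, n = nrow(subgroup),
                 treatments_seen = unique(subgroup$treatment)),
            class = "q_model")
}

#' @export
print.q_model <- function(x, ...) {
  cat(sprintf("Q model (%s), n = %d\n", x$stratum, x$n))
  if (is.null(x$fit$constant)) print(round(x$fit$coefficients, 4))
  else cat(sprintf("  degenerate fit: constant outcome %g\n", x$fit$constant))
  invisible(x)
}

#' @export
coef.q_model <- function(object, ...) object$fit$coefficients

#' G-computation estimate of a stratum potential-outcome mean
#'
#' Predicts every subject's outcome from the fitted Q model with treatment
#' forced to `set_treatment` (own covariates retained) and averages the
#' predictions: the standardization estimate of E[Y^t | stratum].
#'
#' @param qmodel a fitted [fit_q_model()] object.
#' @param subgroup cohort rows to standardize over (normally the same
#'   stratum the model was fitted on).
#' @param set_treatment treatment label to force, or `NULL` to predict at
#'   each subject's factual treatment.
#' @return the mean predicted outcome, a probability.
#' @export
gcomp_mean <- function(qmodel, subgroup, set_treatment) {
  stopifnot(inherits(qmodel, "q_model"))
  if (!is.null(set_treatment) &&
      !set_treatment %in% qmodel$space$treatments) {
    stopf("treatment '%s' is outside the action space", set_treatment)
  }
  if (!nrow(subgroup)) return(NA_real_)
  x <- q_design(subgroup, qmodel$q_spec, qmodel$space, set_treatment)
  mean(predict_logistic(qmodel$fit, x))
}

#' Estimated mean outcome of the rule arm
#'
#' Implements the stratum decomposition of the rule arm's potential-outcome
#' mean: subjects are stratified by predicted risk against the rule's
#' cutoff, each stratum's mean under the assigned treatment is estimated by
#' g-computation, and the strata are combined with their empirical weights.
#' Early-event subjects (event within the grace period) contribute their
#' factual outcome of 1 to their stratum's mean with ordinary 1/n weight
#' and are excluded from the Q-model fits. Subjects whose factual treatment
#' lies outside the action space are likewise excluded from fitting but
#' still receive a standardized prediction.
#'
#' @param cohort eligible cohort data frame (apply eligibility first).
#' @param risks predicted risks aligned with `cohort` rows.
#' @param rule a [decision_rule()]; [factual_rule()] reproduces the
#'   observed event proportion.
#' @param q_spec a [q_model_spec()].
#' @param spec an [eligibility_spec()] (grace period).
#' @return list of class `rule_mean` with `mean` (the estimate of
#'   E[Y^pred]), `strata` (per-stratum decomposition: size, weight,
#'   assigned treatment, estimated mean), `n`, `n_early`.
#' @export
estimate_rule_mean <- function(cohort, risks, rule, q_spec,
                               spec = eligibility_spec()) {
  stopifnot(inherits(rule, "decision_rule"), inherits(q_spec, "q_model_spec"))
  validate_cohort(cohort, q_spec$covariates)
  n <- nrow(cohort)
  if (!n) stopf("empty cohort")
  if (length(risks) != n) {
    stopf("risks (%d) not aligned with cohort rows (%d)", length(risks), n)
  }
  part <- grace_period_partition(cohort, spec)
  space <- rule$space

  if (is_factual_rule(rule)) {
    strata_def <- list(all = seq_len(n))
    assigned <- c(all = NA_character_)
  } else {
    high <- risks >= rule$cutoff
    strata_def <- list(low = which(!high), high = which(high))
    assigned <- c(low = rule$low, high = rule$high)
  }

  rows <- lapply(names(strata_def), function(s) {
    idx <- strata_def[[s]]
    n_s <- length(idx)
    if (!n_s) {
      return(data.frame(stratum = s, n = 0L, n_early = 0L,
                        weight = 0, treatment = assigned[[s]],
                        mean = NA_real_, stringsAsFactors = FALSE))
    }
    early_s <- intersect(idx, part$early_idx)
    main_s <- setdiff(idx, part$early_idx)
    total <- length(early_s) * 1            # factual Y = 1, bypassing the Q model
    if (length(main_s)) {
      fit_rows <- main_s[cohort$treatment[main_s] %in% space$treatments]
      set_t <- if (is_factual_rule(rule)) NULL else assigned[[s]]
      outcome_varies <- length(unique(cohort$outcome[fit_rows])) > 1L
      if (!is.null(set_t) && outcome_varies &&
          !set_t %in% cohort$treatment[fit_rows]) {
        stopf("positivity failure in %s stratum: no subject received '%s'",
              s, set_t)
      }
      qm <- fit_q_model(cohort[fit_rows, , drop = FALSE], q_spec, space,
                        stratum = paste0(s, " stratum"))
      preds_mean <- gcomp_mean(qm, cohort[main_s, , drop = FALSE], set_t)
      total <- total + preds_mean * length(main_s)
    }
    data.frame(stratum = s, n = n_s, n_early = length(early_s),
               weight = n_s / n, treatment = assigned[[s]],
               mean = total / n_s, stringsAsFactors = FALSE)
  })
  strata <- do.call(rbind, rows)
  est <- sum(strata$weight * strata$mean, na.rm = TRUE)
  structure(list(mean = est, strata = strata, n = n,
                 n_early = length(part$early_idx), rule = rule),
            class = "rule_mean")
}

#' @export
print.rule_mean <- function(x, ...) {
  cat(sprintf("Rule-arm mean (%s): %.4f over %d subjects (%d early events)\n",
              format(x$rule), x$mean, x$n, x$n_early))
  print.data.frame(transform(x$strata, mean = round(mean, 4),
                             weight = round(weight, 4)), row.names = FALSE)
  invisible(x)
}

#' Estimated mean outcome of the standard-of-care arm
#'
#' The standard-of-care arm is the observed eligible population itself, so
#' its potential-outcome mean is the plain event proportion over all
#' eligible subjects, regardless of treatment; early events are included
#' (they belong to both arms).
#'
#' @param cohort eligible cohort data frame.
#' @param spec an [eligibility_spec()] (unused beyond validation; kept so
#'   both arms share one interface).
#' @return the event proportion.
#' @export
estimate_soc_mean <- function(cohort, spec = eligibility_spec()) {
  if (!nrow(cohort)) stopf("cannot estimate the standard-of-care mean of an empty cohort")
  mean(cohort$outcome)
}

#' Emulate the target trial: intention-to-treat contrast of rule vs. standard of care
#'
#' The central fitting function of the package. Estimates the rule arm's
#' mean by per-stratum g-computation ([estimate_rule_mean()]), the
#' standard-of-care arm's mean as the observed event proportion
#' ([estimate_soc_mean()]), and their difference, the intention-to-treat
#' estimand Delta = E[Y^pred] - E[Y^soc]. A negative Delta favours the
#' decision rule (fewer adverse events than standard practice). Because
#' every subject contributes to the standard-of-care arm and eligible
#' subjects also contribute to the rule arm, the two arm estimates are
#' dependent; interval estimation must resample whole subjects
#' ([bootstrap_delta()], or `n_boot` here).
#'
#' @inheritParams estimate_rule_mean
#' @param n_boot number of bootstrap replicates for a percentile confidence
#'   interval; 0 (default) skips inference.
#' @param level confidence level for the bootstrap interval.
#' @param boot_seed seed for the bootstrap resampling.
#' @param diagnostics compute the per-cell positivity report (default TRUE;
#'   bootstrap replicates skip it, the estimates are unaffected).
#' @return object of class `rule_emulation`: arm means, `delta`, the
#'   stratum decomposition, counts, a positivity report, and (when
#'   requested) the bootstrap result.
#' @examples
#' cfg <- sim_config(2000, list(list(name = "x", dist = "bernoulli", prob = 0.5)),
#'                   risk_coefficients = c(-1.5, 1),
#'                   treatment_effect = -0.8,
#'                   confounding_coefficients = c(-0.5, 1), seed = 7)
#' sim <- simulate_cohort(cfg)
#' rm_ <- risk_model("x", c(-1.5, 1))
#' risks <- predict(rm_, sim$cohort)
#' rule <- decision_rule(0.25, low = "A", high = "B")
#' fit <- estimate_delta(sim$cohort, risks, rule, q_model_spec("x"))
#' fit
#' @export
estimate_delta <- function(cohort, risks, rule, q_spec,
                           spec = eligibility_spec(),
                           n_boot = 0L, level = 0.95, boot_seed = 1L,
                           diagnostics = TRUE) {
  arm_pred <- estimate_rule_mean(cohort, risks, rule, q_spec, spec)
  arm_soc <- estimate_soc_mean(cohort, spec)
  strata <- arm_pred$strata
  res <- structure(
    list(mean_pred_arm = arm_pred$mean,
         mean_soc_arm = arm_soc,
         delta = arm_pred$mean - arm_soc,
         strata = strata,
         stratum_weights = setNames(strata$weight, strata$stratum),
         n_eligible = arm_pred$n,
         n_low = if ("low" %in% strata$stratum)
           strata$n[strata$stratum == "low"] else NA_integer_,
         n_high = if ("high" %in% strata$stratum)
           strata$n[strata$stratum == "high"] else NA_integer_,
         n_early = arm_pred$n_early,
         positivity = if (diagnostics)
           check_positivity(cohort, risks, rule, q_spec),
         rule = rule, q_spec = q_spec, spec = spec,
         bootstrap = NULL,
         call = match.call()),
    class = "rule_emulation")
  if (n_boot >= 2L) {
    res$bootstrap <- bootstrap_delta(cohort, risks, rule, q_spec, spec,
                                     n_boot = n_boot, seed = boot_seed,
                                     level = level)
  }
  res
}

#' @export
print.rule_emulation <- function(x, digits = 4, ...) {
  cat("Emulated target trial: prediction-based rule vs. standard of care\n")
  cat(sprintf("  rule: %s\n", format(x$rule)))
  cat(sprintf("  eligible subjects: %d (early events in both arms: %d)\n",
              x$n_eligible, x$n_early))
  cat(sprintf("  rule-arm mean      E[Y^pred]: %.*f\n", digits, x$mean_pred_arm))
  cat(sprintf("  standard-of-care   E[Y^soc] : %.*f\n", digits, x$mean_soc_arm))
  cat(sprintf("  intention-to-treat Delta    : %+.*f\n", digits, x$delta))
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  %d%% bootstrap CI: [%+.*f, %+.*f] (%d replicates, %d failed)\n",
                round(100 * x$bootstrap$level), digits, x$bootstrap$ci_lower,
                digits, x$bootstrap$ci_upper, x$bootstrap$n_boot,
                x$bootstrap$n_failed))
  }
  if (!is.null(x$positivity) && any(x$positivity$hard_flag)) {
    cat("  WARNING: positivity concerns; see $positivity\n")
  }
  invisible(x)
}

#' @export
summary.rule_emulation <- function(object, ...) {
  structure(list(fit = object), class = "summary.rule_emulation")
}

#' @export
print.summary.rule_emulation <- function(x, ...) {
  print(x$fit)
  cat("\nStratum decomposition of the rule arm:\n")
  print.data.frame(transform(x$fit$strata, mean = round(mean, 4),
                             weight = round(weight, 4)), row.names = FALSE)
  if (!is.null(x$fit$positivity)) {
    cat("\nPositivity diagnostics:\n")
    print(x$fit$positivity)
  }
  invisible(x)
}

#' @export
coef.rule_emulation <- function(object, ...) {
  c(mean_pred_arm = object$mean_pred_arm,
    mean_soc_arm = object$mean_soc_arm,
    delta = object$delta)
}

#' @export
confint.rule_emulation <- function(object, parm = "delta", level = 0.95, ...) {
  if (is.null(object$bootstrap)) {
    stopf("no bootstrap stored; rerun with n_boot > 0 or call bootstrap_delta()")
  }
  if (!isTRUE(all.equal(level, object$bootstrap$level))) {
    stopf("stored bootstrap interval is at level %g", object$bootstrap$level)
  }
  matrix(c(object$bootstrap$ci_lower, object$bootstrap$ci_upper), 1, 2,
         dimnames = list("delta", sprintf("%g %%", 100 * c((1 - level) / 2,
                                                           1 - (1 - level) / 2))))
}

#' Positivity diagnostics for a rule on a cohort
#'
#' For each risk stratum and each Q-model covariate cell (discrete
#' covariates by their levels; continuous covariates by deciles), counts
#' the subjects who factually received the treatment the rule assigns to
#' that stratum. Cells with fewer than `floor` such subjects are flagged; a
#' stratum in which nobody received the assigned treatment is a hard flag.
#' Empty strata are reported with size 0 and not flagged. Purely
#' diagnostic: nothing is altered.
#'
#' @inheritParams estimate_rule_mean
#' @param floor minimum acceptable per-cell count (default 5).
#' @return object of class `positivity_report`: a data frame with one row
#'   per stratum x covariate cell, plus stratum-level rows (`covariate =
#'   "(stratum)"`), and columns `n_cell`, `n_assigned`, `flag`,
#'   `hard_flag`.
#' @export
check_positivity <- function(cohort, risks, rule, q_spec, floor = 5L) {
  stopifnot(inherits(rule, "decision_rule"))
  if (is_factual_rule(rule)) {
    out <- data.frame(stratum = "all", covariate = "(stratum)", cell = "",
                      n_cell = nrow(cohort), n_assigned = nrow(cohort),
                      flag = FALSE, hard_flag = FALSE,
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("positivity_report", "data.frame"),
                     floor = floor))
  }
  high <- risks >= rule$cutoff
  strata_def <- list(low = which(!high), high = which(high))
  assigned <- c(low = rule$low, high = rule$high)
  rows <- list()
  for (s in names(strata_def)) {
    idx <- strata_def[[s]]
    n_s <- length(idx)
    got <- sum(cohort$treatment[idx] == assigned[[s]])
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = s, covariate = "(stratum)", cell = "",
      n_cell = n_s, n_assigned = got,
      flag = n_s > 0 && got < floor,
      hard_flag = n_s > 0 && got == 0, stringsAsFactors = FALSE)
    if (!n_s) next
    for (v in q_spec$covariates) {
      xv <- cohort[[v]][idx]
      vals <- unique(xv)
      if (is.numeric(xv) && length(vals) > 10L) {
        br <- unique(stats::quantile(xv, seq(0, 1, 0.1)))
        cell <- cut(xv, breaks = br, include.lowest = TRUE)
      } else {
        cell <- factor(xv)
      }
      for (lv in levels(cell)) {
        in_cell <- which(cell == lv)
        got_c <- sum(cohort$treatment[idx][in_cell] == assigned[[s]])
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = s, covariate = v, cell = lv,
          n_cell = length(in_cell), n_assigned = got_c,
          flag = length(in_cell) > 0 && got_c < floor,
          hard_flag = length(in_cell) > 0 && got_c == 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(do.call(rbind, rows),
            class = c("positivity_report", "data.frame"), floor = floor)
}

#' @export
print.positivity_report <- function(x, ...) {
  n_flag <- sum(x$flag)
  cat(sprintf("Positivity report (floor %d): %d of %d cells flagged%s\n",
              attr(x, "floor"), n_flag, nrow(x),
              if (any(x$hard_flag)) "; HARD flags present" else ""))
  if (n_flag) print.data.frame(x[x$flag, , drop = FALSE], row.names = FALSE)
  invisible(x)
}
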