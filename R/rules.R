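# Action space, decision rules, rule enumeration and rule optimization.
#
# A decision rule here is deterministic and one-dimensional: a cutoff on the
# prognostic risk score splits subjects into a low and a high stratum, and
# each stratum is mapped to one treatment from the action space. Expert
# constraints ("combination therapy must not be given to low-risk
# patients") prune the admissible set before optimization.

#' Action space of treatment decisions
#'
#' @param treatments ordered character vector of at least two distinct
#'   treatment labels; the first is the reference treatment used for
#'   regression coding. Defaults to `A` (monotherapy) and `B` (combination
#'   therapy).
#' @return an object of class `action_space`.
#' @export
action_space <- function(treatments = c("A", "B")) {
  treatments <- as.character(treatments)
  if (length(treatments) < 2L || anyDuplicated(treatments)) {
    stopf("action space needs at least two distinct treatment labels")
  }
  structure(list(treatments = treatments), class = "action_space")
}

#' @export
print.action_space <- function(x, ...) {
  cat("Action space:", paste(x$treatments, collapse = ", "), "\n")
  invisible(x)
}

#' A prediction-based decision rule
#'
#' Subjects with predicted risk at or above `cutoff` are labelled high risk
#' (the stratum boundary is closed on the high side) and receive the `high`
#' treatment; everyone else receives the `low` treatment.
#'
#' @param cutoff risk cutoff in `[0, 1]`.
#' @param low,high treatment labels assigned to the low- and high-risk
#'   stratum; must belong to `space`.
#' @param space an [action_space()].
#' @return an object of class `decision_rule`.
#' @export
decision_rule <- function(cutoff, low, high, space = action_space()) {
  stopifnot(inherits(space, "action_space"))
  if (cutoff < 0 || cutoff > 1) stopf("cutoff must lie in [0, 1]")
  bad <- setdiff(c(low, high), space$treatments)
  if (length(bad)) {
    stopf("treatment(s) outside the action space: %s", paste(bad, collapse = ", "))
  }
  structure(list(cutoff = cutoff, low = low, high = high, space = space),
            class = "decision_rule")
}

#' The standard-practice reference rule: everyone keeps their factual treatment
#'
#' A degenerate rule used for diagnostics: g-computation under it reproduces
#' the observed event proportion, so the estimated contrast against the
#' standard-of-care arm is exactly zero.
#'
#' @param space an [action_space()].
#' @return a `decision_rule` whose assignment is each subject's observed
#'   treatment.
#' @export
factual_rule <- function(space = action_space()) {
  r <- decision_rule(1, space$treatments[1], space$treatments[1], space)
  r$factual <- TRUE
  r
}

is_factual_rule <- function(rule) isTRUE(rule$factual)

#' @export
print.decision_rule <- function(x, ...) {
  if (is_factual_rule(x)) {
    cat("Decision rule: every subject keeps the factual treatment\n")
  } else {
    cat(sprintf("Decision rule: risk < %g -> %s, risk >= %g -> %s\n",
                x$cutoff, x$low, x$cutoff, x$high))
  }
  invisible(x)
}

#' @export
format.decision_rule <- function(x, ...) {
  if (is_factual_rule(x)) "factual" else
    sprintf("cutoff=%g, low=%s, high=%s", x$cutoff, x$low, x$high)
}

#' Expert-opinion constraints on rules
#'
#' @param forbid a list of `c(stratum, treatment)` pairs (stratum is
#'   `"low"` or `"high"`) that no admissible rule may contain, e.g.
#'   `list(c("low", "B"))` to forbid escalating low-risk patients to
#'   combination therapy.
#' @param space an [action_space()].
#' @return an object of class `rule_constraint`.
#' @export
rule_constraint <- function(forbid = list(), space = action_space()) {
  for (f in forbid) {
    if (length(f) != 2L || !f[1] %in% c("low", "high")) {
      stopf("each constraint must be a (stratum, treatment) pair")
    }
    if (!f[2] %in% space$treatments) {
      stopf("constraint references treatment '%s' outside the action space", f[2])
    }
  }
  structure(list(forbid = forbid, space = space), class = "rule_constraint")
}

#' Apply a decision rule to risk scores
#'
#' @param rule a [decision_rule()].
#' @param risks numeric vector of risks in `[0, 1]`.
#' @return character vector of assigned treatment labels.
#' @export
apply_rule <- function(rule, risks) {
  stopifnot(inherits(rule, "decision_rule"))
  if (any(risks < 0 | risks > 1, na.rm = TRUE)) {
    stopf("risks must lie in [0, 1]")
  }
  ifelse(risks >= rule$cutoff, rule$high, rule$low)
}

#' Enumerate the admissible candidate rules
#'
#' Builds the Cartesian product of the cutoff grid with all stratum-to-
#' treatment assignments, removes assignments hitting a constraint, and
#' deduplicates constant rules (rules giving both strata the same
#' treatment), which do not depend on the cutoff and are kept once, at
#' cutoff 1. Constant rules are retained so the "treat everyone with A/B"
#' baselines are always among the scored candidates.
#'
#' @param space an [action_space()].
#' @param cutoff_grid numeric vector of candidate cutoffs in `[0, 1]`.
#' @param constraints a [rule_constraint()] or NULL.
#' @return a list of [decision_rule()] objects.
#' @export
enumerate_rules <- function(space = action_space(), cutoff_grid,
                            constraints = NULL) {
  stopifnot(inherits(space, "action_space"))
  if (!length(cutoff_grid) || any(cutoff_grid < 0 | cutoff_grid > 1)) {
    stopf("cutoff_grid must be non-empty and within [0, 1]")
  }
  forbidden <- function(low, high) {
    if (is.null(constraints)) return(FALSE)
    any(vapply(constraints$forbid, function(f) {
      (f[1] == "low" && f[2] == low) || (f[1] == "high" && f[2] == high)
    }, logical(1)))
  }
  rules <- list()
  trts <- space$treatments
  for (low in trts) for (high in trts) {
    if (forbidden(low, high)) next
    if (low == high) {
      rules[[length(rules) + 1L]] <- decision_rule(1, low, high, space)
    } else {
      for (cut in sort(cutoff_grid)) {
        rules[[length(rules) + 1L]] <- decision_rule(cut, low, high, space)
      }
    }
  }
  if (!length(rules)) stopf("constraints leave no admissible rule")
  rules
}

#' Optimize the decision rule on the optimization sample
#'
#' Scores every candidate rule with the same per-stratum g-computation
#' estimator used at validation ([estimate_rule_mean()]), transforms the
#' estimated event proportion through the utility (default: the proportion
#' itself, to be minimized), and returns the utility-minimizing rule.
#' Candidates whose strata lack positivity for the assigned treatment are
#' flagged unevaluable and skipped with a warning. Ties are broken toward
#' the larger cutoff (fewer subjects escalated), then by the alphabetical
#' order of the (low, high) assignment.
#'
#' @param candidates list of [decision_rule()] objects.
#' @param cohort eligible cohort data frame.
#' @param risks predicted risks aligned with `cohort`.
#' @param q_spec a [q_model_spec()].
#' @param spec an [eligibility_spec()] (for grace-period handling).
#' @param utility function mapping the estimated event proportion to a
#'   scalar loss to be minimized; default identity.
#' @return list of class `rule_optimization` with `best` (the selected
#'   rule), `scores` (one row per candidate: rule, estimated event
#'   proportion, utility, evaluable flag).
#' @export
optimize_rule <- function(candidates, cohort, risks, q_spec,
                          spec = eligibility_spec(), utility = identity) {
  if (!length(candidates)) stopf("no candidate rules supplied")
  scores <- data.frame(
    rule = vapply(candidates, format, ""),
    cutoff = vapply(candidates, `[[`, 0, "cutoff"),
    low = vapply(candidates, `[[`, "", "low"),
    high = vapply(candidates, `[[`, "", "high"),
    event_proportion = NA_real_, utility = NA_real_, evaluable = FALSE,
    stringsAsFactors = FALSE
  )
  for (k in seq_along(candidates)) {
    est <- tryCatch(
      estimate_rule_mean(cohort, risks, candidates[[k]], q_spec, spec),
      error = function(e) e
    )
    if (inherits(est, "error")) {
      warnf("candidate %d (%s) unevaluable: %s", k,
            scores$rule[k], conditionMessage(est))
      next
    }
    scores$event_proportion[k] <- est$mean
    scores$utility[k] <- utility(est$mean)
    scores$evaluable[k] <- TRUE
  }
  if (!any(scores$evaluable)) {
    stopf("no candidate rule was evaluable (positivity failed everywhere)")
  }
  ev <- which(scores$evaluable)
  ord <- ev[order(scores$utility[ev], -scores$cutoff[ev],
                  scores$low[ev], scores$high[ev])]
  best_idx <- ord[1]
  structure(list(best = candidates[[best_idx]], best_index = best_idx,
                 scores = scores),
            class = "rule_optimization")
}

#' @export
print.rule_optimization <- function(x, ...) {
  cat("Rule optimization over", nrow(x$scores), "candidates\n")
  print.data.frame(
    transform(x$scores,
              event_proportion = round(event_proportion, 4),
              utility = round(utility, 4)),
    row.names = FALSE)
  cat("Selected:", format(x$best), "\n")
  invisible(x)
}

#' Write / read decision rules as structured text records
#'
#' @param rules a single rule or list of rules.
#' @param path file path.
#' @export
write_rules <- function(rules, path) {
  if (inherits(rules, "decision_rule")) rules <- list(rules)
  yaml::write_yaml(lapply(rules, function(r)
    list(cutoff = r$cutoff, low = r$low, high = r$high,
         treatments = as.list(r$space$treatments))), path)
  invisible(path)
}

#' @rdname write_rules
#' @return `read_rules` returns a list of `decision_rule` objects.
#' @export
read_rules <- function(path) {
  lapply(yaml::read_yaml(path), function(d) {
    decision_rule(d$cutoff, d$low, d$high,
                  action_space(as.character(unlist(d$treatments))))
  })
}
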