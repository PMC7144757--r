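# Benchmark scenarios: fixed data-generating processes used to validate
# the estimators against the simulator's exact potential outcomes. Each
# scenario bundles the generating configuration with the prognostic model,
# rule and Q specification an analysis of it would use, so tests, examples
# and the acceptance script all exercise identical study conditions.

#' Benchmark simulation scenarios
#'
#' Four fixed data-generating processes emulating a register of newly
#' diagnosed patients with a roughly 20% five-year event risk, used to
#' validate the estimators against the simulator's exact potential
#' outcomes:
#'
#' \describe{
#'   \item{`scenario_confounded()`}{Prognostic covariate `x1` (standard
#'     normal, log-odds slope 0.9) drives the risk score; a binary
#'     covariate `x2` both raises the event risk (log-odds 1.9) and
#'     strongly selects patients into combination therapy (log-odds 3), so
#'     treatment is confounded *within* risk strata — the score does not
#'     use `x2`. Combination therapy lowers the event log-odds by 0.8.
#'     `q_spec` adjusts for both covariates (the correct specification);
#'     `q_spec_naive` is the treatment-only model whose stratified means
#'     are biased by construction.}
#'   \item{`scenario_null()`}{The same process with a zero treatment
#'     effect: both potential outcomes coincide subject by subject, so the
#'     true contrast of any rule against standard of care is exactly 0.}
#'   \item{`scenario_interaction()`}{A single covariate `x` with a
#'     qualitative treatment interaction: the benefit of combination
#'     therapy is `-2 x` on the log-odds scale, crossing zero exactly
#'     where the baseline risk equals 0.3. Escalating above a risk cutoff
#'     of 0.3 is therefore truly optimal within `cutoff_grid =
#'     c(0.2, 0.3, 0.4)`; moderately risk-seeking prescribing (log-odds
#'     0.5 per unit `x`) supplies confounding.}
#'   \item{`scenario_beneficial()`}{Combination therapy uniformly lowers
#'     the event log-odds by 1 but standard practice gives it to only ~18%
#'     of patients, haphazardly; escalating all high-risk patients is
#'     clearly beneficial (population contrast about -0.05).}
#' }
#'
#' @param n number of subjects.
#' @param seed simulation seed.
#' @return a list with elements `config` (a [sim_config()]), `risk_model`
#'   (the fixed prognostic model used for stratification), `rule` (the
#'   decision rule under evaluation), `q_spec` (the adjustment set), and
#'   scenario-specific extras (`q_spec_naive`, `cutoff_grid`,
#'   `optimal_cutoff`).
#' @examples
#' sc <- scenario_confounded(n = 2000, seed = 1)
#' sim <- simulate_cohort(sc$config)
#' risks <- predict(sc$risk_model, sim$cohort)
#' estimate_delta(sim$cohort, risks, sc$rule, sc$q_spec)
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_confounded <- function(n = 5000, seed = 1) {
  list(
    config = sim_config(
      n_subjects = n,
      covariates = list(list(name = "x1", dist = "normal"),
                        list(name = "x2", dist = "bernoulli", prob = 0.5)),
      risk_coefficients = c(-2.4, 0.9, 1.9),
      treatment_effect = -0.8,
      confounding_coefficients = c(-1.5, 0, 3),
      seed = seed),
    risk_model = risk_model("x1", c(-1.4, 0.9)),
    rule = decision_rule(0.3, "A", "B"),
    q_spec = q_model_spec(c("x1", "x2")),
    q_spec_naive = q_model_spec(character(0))
  )
}

#' @rdname scenarios
#' @export
scenario_null <- function(n = 5000, seed = 1) {
  sc <- scenario_confounded(n, seed)
  sc$config$treatment_effect <- 0
  sc
}

#' @rdname scenarios
#' @export
scenario_interaction <- function(n = 5000, seed = 1) {
  list(
    config = sim_config(
      n_subjects = n,
      covariates = list(list(name = "x", dist = "normal")),
      risk_coefficients = c(stats::qlogis(0.3), 1),
      treatment_effect = 0,
      effect_interaction = c(x = -2),
      confounding_coefficients = c(0, 0.5),
      seed = seed),
    risk_model = risk_model("x", c(stats::qlogis(0.3), 1)),
    rule = decision_rule(0.3, "A", "B"),
    q_spec = q_model_spec("x", interactions = "x"),
    cutoff_grid = c(0.2, 0.3, 0.4),
    optimal_cutoff = 0.3
  )
}

#' @rdname scenarios
#' @export
scenario_beneficial <- function(n = 5000, seed = 1) {
  list(
    config = sim_config(
      n_subjects = n,
      covariates = list(list(name = "x1", dist = "normal")),
      risk_coefficients = c(-1.2, 1),
      treatment_effect = -1,
      confounding_coefficients = c(-1.5, 0),
      seed = seed),
    risk_model = risk_model("x1", c(-1.2, 1)),
    rule = decision_rule(0.3, "A", "B"),
    q_spec = q_model_spec("x1")
  )
}
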