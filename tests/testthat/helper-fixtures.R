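# Shared fixture builders. All data is generated in code.

# Minimal hand-assembled cohort: one binary covariate, all four
# treatment-by-covariate cells occupied, outcomes chosen so standardized
# means are easy to enumerate by hand.
toy_cohort <- function() {
  # 3 subjects per (x, treatment) cell; cell event rates kept strictly
  # inside (0, 1) so the saturated logistic fit is well defined:
  #   x=0: A -> 1/3, B -> 1/3;  x=1: A -> 2/3, B -> 1/3
  data.frame(
    id = paste0("t", 1:12),
    x = rep(c(0, 1), each = 6),
    treatment = rep(c("A", "A", "A", "B", "B", "B"), 2),
    treatment_start_offset_days = 0L,
    outcome = c(1L, 0L, 0L, 0L, 0L, 1L,
                1L, 1L, 0L, 1L, 0L, 0L),
    event_offset_days = c(500L, NA, NA, NA, NA, 800L,
                          900L, 1000L, NA, 700L, NA, NA),
    stringsAsFactors = FALSE
  )
}

# One-binary-confounder configuration: x raises both the event risk and
# the probability of combination therapy, so treatment is confounded.
confounded_config <- function(n = 5000, seed = 1,
                              treatment_effect = -0.8) {
  sim_config(
    n_subjects = n,
    covariates = list(list(name = "x", dist = "bernoulli", prob = 0.5)),
    risk_coefficients = c(-1.5, 1.5),
    treatment_effect = treatment_effect,
    confounding_coefficients = c(-1, 2),
    seed = seed
  )
}

# Two-covariate configuration: x1 is prognostic (drives the risk score),
# x2 is a confounder (drives both treatment and outcome) that the risk
# model ignores, so confounding persists within risk strata.
two_cov_config <- function(n = 5000, seed = 1, treatment_effect = -0.8) {
  sim_config(
    n_subjects = n,
    covariates = list(list(name = "x1", dist = "normal", mean = 0, sd = 1),
                      list(name = "x2", dist = "bernoulli", prob = 0.5)),
    risk_coefficients = c(-1.8, 0.9, 1.1),
    treatment_effect = treatment_effect,
    confounding_coefficients = c(-1, 0, 2),
    seed = seed
  )
}

# The risk model aligned with two_cov_config's generating coefficients
# (x1 only: the score a prognostic model without access to x2 would use is
# misspecified; for stratification we use the full generating model).
two_cov_risk_model <- function() {
  risk_model(c("x1", "x2"), c(-1.8, 0.9, 1.1))
}

# Brute-force nonparametric standardization over a discrete covariate:
# sum_x Phat(X = x) * mean(Y | T = t, X = x). Independent oracle for
# gcomp_mean with a saturated Q model.
standardize_by_hand <- function(cohort, covariate, set_treatment) {
  vals <- unique(cohort[[covariate]])
  p <- vapply(vals, function(v) mean(cohort[[covariate]] == v), 0)
  m <- vapply(vals, function(v) {
    sel <- cohort[[covariate]] == v & cohort$treatment == set_treatment
    mean(cohort$outcome[sel])
  }, 0)
  sum(p * m)
}

# Random but seeded fraction triples for property tests over split plans.
with_seed_fractions <- function(s) {
  set.seed(s)
  f <- runif(3)
  f / sum(f)
}

# A small end-to-end pipeline configuration over the two-covariate
# confounded scenario, as the nested list run_pipeline() accepts.
pipeline_test_config <- function(n = 3000, seed = 12) {
  list(
    seed = seed,
    simulation = list(
      n_subjects = n,
      covariates = list(list(name = "x1", dist = "normal", mean = 0, sd = 1),
                        list(name = "x2", dist = "bernoulli", prob = 0.5)),
      risk_coefficients = list(-1.8, 0.9, 1.1),
      treatment_effect = -0.8,
      confounding_coefficients = list(-1, 0, 2)
    ),
    eligibility = list(grace_period_days = 14, horizon_days = 1826),
    split = list(fractions = list(0.4, 0.3, 0.3), mode = "three-way"),
    risk_model = list(covariates = list("x1", "x2")),
    rules = list(cutoff_grid = list(0.2, 0.3, 0.4),
                 constraints = list(list(stratum = "low", treatment = "B"))),
    q_model = list(covariates = list("x1", "x2")),
    bootstrap = list(n_boot = 40, level = 0.95)
  )
}

# Rebuild the sim_config a pipeline configuration implies (mirrors the
# pipeline's own translation; kept in test code so tests can reproduce the
# cohort a config generates).
config_from <- function(cfg) {
  s <- cfg$simulation
  sim_config(
    n_subjects = s$n_subjects,
    covariates = s$covariates,
    risk_coefficients = as.numeric(unlist(s$risk_coefficients)),
    treatment_effect = s$treatment_effect,
    confounding_coefficients = as.numeric(unlist(s$confounding_coefficients)),
    seed = cfg$seed
  )
}

# Large-sample oracle for the population Delta of a scenario: simulate a
# big cohort once and use exact potential outcomes.
oracle_delta <- function(config_fun, rule, risk_mod, n = 400000, seed = 777) {
  cfg <- config_fun(n = n, seed = seed)
  sim <- simulate_cohort(cfg)
  risks <- predict(risk_mod, sim$cohort)
  true_rule_value(sim, rule, risks) - mean(sim$cohort$outcome)
}
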