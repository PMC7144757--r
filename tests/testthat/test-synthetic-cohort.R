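test_that("configuration invariants are enforced", {
  covs <- list(list(name = "x", dist = "bernoulli", prob = 0.5))
  expect_error(sim_config(0, covs, c(0, 0), confounding_coefficients = c(0, 0)),
               "n_subjects")
  expect_error(sim_config(10, covs, c(0), confounding_coefficients = c(0, 0)),
               "risk_coefficients")
  expect_error(sim_config(10, covs, c(0, 0), confounding_coefficients = c(0)),
               "confounding_coefficients")
  expect_error(sim_config(10, list(list(name = "x", dist = "gamma")),
                          c(0, 0), confounding_coefficients = c(0, 0)),
               "distribution family")
  expect_error(sim_config(10, covs, c(0, 0), confounding_coefficients = c(0, 0),
                          grace_period_days = 2000),
               "grace_period_days")
  expect_error(sim_config(10, covs, c(0, 0), confounding_coefficients = c(0, 0),
                          effect_interaction = c(zz = 1)),
               "effect_interaction")
})

test_that("null treatment effect gives identical potential outcomes per subject", {
  cfg <- confounded_config(n = 2000, seed = 3, treatment_effect = 0)
  sim <- simulate_cohort(cfg)
  expect_identical(sim$potential$y_under_A, sim$potential$y_under_B)
})

test_that("zero coefficients give true risk exactly one half", {
  cfg <- sim_config(500, list(list(name = "x", dist = "normal")),
                    risk_coefficients = c(0, 0),
                    confounding_coefficients = c(0, 0), seed = 5)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$potential$true_risk == 0.5))
})

test_that("treatment assignment follows the logistic confounding model", {
  # Monte-Carlo check against the closed-form logistic probability
  cfg <- sim_config(100000,
                    list(list(name = "x", dist = "bernoulli", prob = 0.5)),
                    risk_coefficients = c(-1, 0.5),
                    confounding_coefficients = c(-0.7, 1.3), seed = 9)
  sim <- simulate_cohort(cfg)
  p_b_x1 <- mean(sim$cohort$treatment[sim$cohort$x == 1] == "B")
  p_b_x0 <- mean(sim$cohort$treatment[sim$cohort$x == 0] == "B")
  expect_lt(abs(p_b_x1 - plogis(-0.7 + 1.3)), 0.01)
  expect_lt(abs(p_b_x0 - plogis(-0.7)), 0.01)
})

test_that("consistency holds: observed outcome equals the received potential outcome", {
  sim <- simulate_cohort(two_cov_config(n = 3000, seed = 21))
  y_pot <- ifelse(sim$cohort$treatment == "B",
                  sim$potential$y_under_B, sim$potential$y_under_A)
  expect_identical(sim$cohort$outcome, as.integer(y_pot))
  expect_true(all(sim$potential$true_risk >= 0 & sim$potential$true_risk <= 1))
  expect_false(anyDuplicated(sim$cohort$id) > 0)
  ev <- sim$cohort$outcome == 1
  expect_true(all(sim$cohort$event_offset_days[ev] >= 0))
  expect_true(all(sim$cohort$event_offset_days[ev] <= sim$config$horizon_days))
  expect_true(all(is.na(sim$cohort$event_offset_days[!ev])))
  expect_true(all(sim$cohort$treatment_start_offset_days %in%
                    0:sim$config$grace_period_days))
})

test_that("zero confounding coefficients decouple covariates from treatment", {
  cfg <- sim_config(100000,
                    list(list(name = "x", dist = "normal")),
                    risk_coefficients = c(-1, 1),
                    confounding_coefficients = c(0, 0), seed = 13)
  sim <- simulate_cohort(cfg)
  expect_lt(abs(cor(sim$cohort$x, as.numeric(sim$cohort$treatment == "B"))), 0.02)
})

test_that("same seed reproduces the cohort; covariate streams are independent", {
  cfg <- confounded_config(n = 500, seed = 42)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$potential, s2$potential)

  # adding a covariate (with zero coefficients) must not perturb the
  # outcome or assignment streams of the original covariate set
  cfg2 <- sim_config(
    500,
    covariates = list(list(name = "x", dist = "bernoulli", prob = 0.5),
                      list(name = "z", dist = "normal")),
    risk_coefficients = c(-1.5, 1.5, 0),
    treatment_effect = -0.8,
    confounding_coefficients = c(-1, 2, 0), seed = 42
  )
  s3 <- simulate_cohort(cfg2)
  expect_identical(s3$cohort$x, s1$cohort$x)
  expect_identical(s3$cohort$outcome, s1$cohort$outcome)
  expect_identical(s3$cohort$treatment, s1$cohort$treatment)
})

test_that("true_rule_value matches degenerate rules and hand enumeration", {
  sim <- simulate_cohort(confounded_config(n = 1000, seed = 8))
  all_A <- decision_rule(1, "A", "A")
  all_B <- decision_rule(0, "B", "B")
  risks <- sim$potential$true_risk
  expect_equal(true_rule_value(sim, all_A, risks), mean(sim$potential$y_under_A))
  expect_equal(true_rule_value(sim, all_B, risks), mean(sim$potential$y_under_B))
  expect_error(true_rule_value(sim, all_A, risks[-1]), "aligned")

  # two-subject toy enumerated by hand
  toy <- list(
    cohort = data.frame(id = c("a", "b"), treatment = c("A", "A"),
                        treatment_start_offset_days = 0L,
                        outcome = c(1L, 0L), event_offset_days = c(10L, NA)),
    potential = data.frame(y_under_A = c(1, 0), y_under_B = c(0, 0),
                           true_risk = c(0.9, 0.1)),
    config = confounded_config(n = 2)
  )
  class(toy) <- "sim_cohort"
  rule <- decision_rule(0.5, "A", "B")
  expect_equal(true_rule_value(toy, rule, c(0.9, 0.1)), 0)
})

test_that("cohort tables round-trip through delimited text", {
  sim <- simulate_cohort(confounded_config(n = 200, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$cohort, path)
  back <- read_cohort(path)
  expect_equal(back, sim$cohort)
  # missing event offsets are empty fields, not the string NA
  raw <- readLines(path)
  expect_false(any(grepl("NA", raw)))
})
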