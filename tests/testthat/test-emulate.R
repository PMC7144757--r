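test_that("eligibility filtering matches hand evaluation and logs exclusions", {
  cohort <- data.frame(id = c("a", "b", "c"), age = c(17, 18, 40),
                       treatment = "A", treatment_start_offset_days = 0L,
                       outcome = c(0L, 0L, 1L),
                       event_offset_days = c(NA, NA, 30L))
  spec <- eligibility_spec(c(adult = "age >= 18"))
  out <- apply_eligibility(cohort, spec)
  expect_equal(out$id, c("b", "c"))
  expect_equal(attr(out, "exclusions"), c(adult = 1L))

  # all-pass predicates are the identity on rows
  out2 <- apply_eligibility(cohort, eligibility_spec(c(any = "age > 0")))
  expect_equal(out2$id, cohort$id)

  # contradictory predicates empty the table with a warning, not an error
  expect_warning(
    out3 <- apply_eligibility(cohort, eligibility_spec(c(a = "age > 20",
                                                         b = "age < 20"))),
    "no subject")
  expect_equal(nrow(out3), 0)

  expect_error(apply_eligibility(cohort, eligibility_spec(c(z = "bmi > 20"))),
               "missing column")
})

test_that("grace-period partition is inclusive at the boundary and conserves subjects", {
  cohort <- data.frame(id = c("a", "b", "c", "d"),
                       treatment = "A", treatment_start_offset_days = 0L,
                       outcome = c(1L, 1L, 1L, 0L),
                       event_offset_days = c(3L, 14L, 15L, NA))
  spec <- eligibility_spec(grace_period_days = 14)
  p <- grace_period_partition(cohort, spec)
  expect_equal(p$early_idx, c(1L, 2L))
  expect_equal(p$main_idx, c(3L, 4L))
  expect_equal(sort(c(p$early_idx, p$main_idx)), 1:4)

  p0 <- grace_period_partition(cohort, eligibility_spec(grace_period_days = 0))
  expect_equal(p0$early_idx, integer(0))
  cohort$event_offset_days[1] <- 0L
  p0b <- grace_period_partition(cohort, eligibility_spec(grace_period_days = 0))
  expect_equal(p0b$early_idx, 1L)

  none <- cohort
  none$outcome <- 0L
  none$event_offset_days <- NA_integer_
  expect_equal(grace_period_partition(none, spec)$early_idx, integer(0))

  bad <- cohort
  bad$event_offset_days[2] <- -1L
  expect_error(grace_period_partition(bad, spec), "non-negative")
})

test_that("Q model recovers the generating treatment effect in a randomized subgroup", {
  cfg <- sim_config(20000,
                    list(list(name = "x", dist = "bernoulli", prob = 0.5)),
                    risk_coefficients = c(-1, 0),   # x has no outcome effect
                    treatment_effect = -0.8,
                    confounding_coefficients = c(0, 0), seed = 61)
  sim <- simulate_cohort(cfg)
  qm <- fit_q_model(sim$cohort, q_model_spec("x"))
  # 3 standard errors of a logistic log-odds-ratio with ~10000 per arm and
  # event rates around 0.27 (A) / 0.16 (B): se ~= 0.04
  expect_lt(abs(coef(qm)[["treatment"]] + 0.8), 0.12)
})

test_that("treatment-only Q model reproduces subgroup treatment means exactly", {
  toy <- toy_cohort()
  qm <- fit_q_model(toy, q_model_spec(character(0)))
  for (t in c("A", "B")) {
    expect_equal(gcomp_mean(qm, toy, t),
                 mean(toy$outcome[toy$treatment == t]), tolerance = 1e-9)
  }
})

test_that("single-treatment subgroups raise a positivity error naming the stratum", {
  toy <- toy_cohort()
  only_A <- toy[toy$treatment == "A", ]
  expect_error(fit_q_model(only_A, q_model_spec("x"), stratum = "low stratum"),
               "positivity.*low stratum|low stratum.*positivity")
  expect_error(gcomp_mean(fit_q_model(toy, q_model_spec("x")), toy, "Z"),
               "outside the action space")
})

test_that("g-computation equals brute-force standardization with a saturated Q model", {
  toy <- toy_cohort()
  qs <- q_model_spec("x", interactions = "x")
  qm <- fit_q_model(toy, qs)
  # hand enumeration of the four cells:
  # E[Y^A] = 0.5 * 1/3 + 0.5 * 2/3 = 0.5 ; E[Y^B] = 0.5 * 1/3 + 0.5 * 1/3
  expect_equal(gcomp_mean(qm, toy, "A"), 0.5, tolerance = 1e-10)
  expect_equal(gcomp_mean(qm, toy, "B"), 1 / 3, tolerance = 1e-10)
  expect_equal(gcomp_mean(qm, toy, "A"),
               standardize_by_hand(toy, "x", "A"), tolerance = 1e-10)
  expect_equal(gcomp_mean(qm, toy, "B"),
               standardize_by_hand(toy, "x", "B"), tolerance = 1e-10)
})

test_that("with randomized treatment a treatment-only Q model reduces to stratified means", {
  cfg <- confounded_config(n = 3000, seed = 71)
  cfg$confounding_coefficients <- c(0, 0)
  sim <- simulate_cohort(cfg)
  qm <- fit_q_model(sim$cohort, q_model_spec(character(0)))
  for (t in c("A", "B")) {
    expect_equal(gcomp_mean(qm, sim$cohort, t),
                 mean(sim$cohort$outcome[sim$cohort$treatment == t]),
                 tolerance = 1e-9)
  }
})

test_that("rule-arm estimate decomposes exactly over strata and handles early events", {
  sim <- simulate_cohort(two_cov_config(n = 4000, seed = 81))
  risks <- predict(two_cov_risk_model(), sim$cohort)
  rule <- decision_rule(0.3, "A", "B")
  est <- estimate_rule_mean(sim$cohort, risks, rule, q_model_spec(c("x1", "x2")))
  expect_equal(est$mean, sum(est$strata$weight * est$strata$mean),
               tolerance = 1e-12)
  expect_equal(sum(est$strata$weight), 1, tolerance = 1e-12)
  expect_equal(sum(est$strata$n), nrow(sim$cohort))

  # a cohort made entirely of early events estimates 1 without any Q model
  early <- data.frame(id = as.character(1:5), treatment = "A",
                      treatment_start_offset_days = 0L, outcome = 1L,
                      event_offset_days = 2L, x1 = rnorm(5), x2 = 1)
  est_early <- estimate_rule_mean(early, rep(0.5, 5), rule,
                                  q_model_spec(c("x1", "x2")))
  expect_equal(est_early$mean, 1.0)
  expect_equal(est_early$n_early, 5L)
})

test_that("early-event subjects enter both arms; removing one changes both arm means", {
  sim <- simulate_cohort(confounded_config(n = 2000, seed = 83))
  cohort <- sim$cohort
  # force a known early event
  cohort$outcome[1] <- 1L
  cohort$event_offset_days[1] <- 5L
  risks <- predict(risk_model("x", c(-1.5, 1.5)), cohort)
  rule <- decision_rule(0.3, "A", "B")
  qs <- q_model_spec("x")
  spec <- eligibility_spec(grace_period_days = 14)
  with_arm <- estimate_rule_mean(cohort, risks, rule, qs, spec)
  with_soc <- estimate_soc_mean(cohort, spec)
  dropped <- cohort[-1, ]
  without_arm <- estimate_rule_mean(dropped, risks[-1], rule, qs, spec)
  without_soc <- estimate_soc_mean(dropped, spec)
  expect_false(isTRUE(all.equal(with_arm$mean, without_arm$mean)))
  expect_false(isTRUE(all.equal(with_soc, without_soc)))
})

test_that("standard-of-care mean is the plain eligible event proportion", {
  cohort <- data.frame(id = as.character(1:4), treatment = "A",
                       treatment_start_offset_days = 0L,
                       outcome = c(1L, 0L, 0L, 1L),
                       event_offset_days = c(100L, NA, NA, 40L))
  expect_equal(estimate_soc_mean(cohort), 0.5)
  cohort0 <- transform(cohort, outcome = 0L, event_offset_days = NA_integer_)
  expect_equal(estimate_soc_mean(cohort0), 0)
  sim <- simulate_cohort(confounded_config(n = 1000, seed = 91))
  expect_identical(estimate_soc_mean(sim$cohort), mean(sim$cohort$outcome))
  expect_error(estimate_soc_mean(cohort[0, ]), "empty")
})

test_that("the factual rule with a saturated Q model gives Delta exactly zero", {
  sim <- simulate_cohort(confounded_config(n = 3000, seed = 95))
  risks <- predict(risk_model("x", c(-1.5, 1.5)), sim$cohort)
  fit <- estimate_delta(sim$cohort, risks, factual_rule(),
                        q_model_spec("x", interactions = "x"))
  expect_equal(fit$delta, 0, tolerance = 1e-8)
  expect_equal(fit$mean_pred_arm, mean(sim$cohort$outcome), tolerance = 1e-8)
})

test_that("cutoff 0 and cutoff 1 reduce to treat-everyone rules", {
  sim <- simulate_cohort(confounded_config(n = 3000, seed = 97))
  risks <- predict(risk_model("x", c(-1.5, 1.5)), sim$cohort)
  qs <- q_model_spec("x")
  all_high <- estimate_rule_mean(sim$cohort, risks, decision_rule(0, "A", "B"), qs)
  const_B <- estimate_rule_mean(sim$cohort, risks, decision_rule(0, "B", "B"), qs)
  expect_equal(all_high$mean, const_B$mean, tolerance = 1e-12)
  expect_equal(all_high$strata$n[all_high$strata$stratum == "low"], 0L)
  # risks are strictly below 1, so cutoff 1 sends everyone to the low arm
  all_low <- estimate_rule_mean(sim$cohort, risks, decision_rule(1, "A", "B"), qs)
  const_A <- estimate_rule_mean(sim$cohort, risks, decision_rule(1, "A", "A"), qs)
  expect_equal(all_low$mean, const_A$mean, tolerance = 1e-12)
})

test_that("estimate_delta assembles a coherent emulation result", {
  sim <- simulate_cohort(two_cov_config(n = 4000, seed = 99))
  risks <- predict(two_cov_risk_model(), sim$cohort)
  fit <- estimate_delta(sim$cohort, risks, decision_rule(0.3, "A", "B"),
                        q_model_spec(c("x1", "x2")))
  expect_s3_class(fit, "rule_emulation")
  expect_equal(fit$delta, fit$mean_pred_arm - fit$mean_soc_arm)
  expect_equal(unname(sum(fit$stratum_weights)), 1, tolerance = 1e-12)
  expect_equal(fit$n_low + fit$n_high, fit$n_eligible)
  expect_true(all(c(fit$mean_pred_arm, fit$mean_soc_arm) >= 0 &
                    c(fit$mean_pred_arm, fit$mean_soc_arm) <= 1))
  expect_equal(unname(coef(fit)),
               c(fit$mean_pred_arm, fit$mean_soc_arm, fit$delta))
  expect_error(confint(fit), "bootstrap")
  expect_output(print(summary(fit)), "Stratum decomposition")
})

test_that("positivity diagnostics flag missing treatments and skip empty strata", {
  cohort <- data.frame(id = as.character(1:40), x = rep(c(0, 1), 20),
                       treatment = "A", treatment_start_offset_days = 0L,
                       outcome = rep(c(0L, 1L), 20),
                       event_offset_days = rep(c(NA, 100L), 20))
  risks <- rep(c(0.1, 0.9), 20)
  rule <- decision_rule(0.5, "A", "B")
  rep_ <- check_positivity(cohort, risks, rule, q_model_spec("x"))
  high_row <- rep_[rep_$stratum == "high" & rep_$covariate == "(stratum)", ]
  expect_true(high_row$hard_flag)   # nobody in the high stratum received B
  low_row <- rep_[rep_$stratum == "low" & rep_$covariate == "(stratum)", ]
  expect_false(low_row$hard_flag)

  # balanced randomized simulation: no flags at n = 5000, floor 5
  cfg <- confounded_config(n = 5000, seed = 101)
  cfg$confounding_coefficients <- c(0, 0)
  sim <- simulate_cohort(cfg)
  risks2 <- predict(risk_model("x", c(-1.5, 1.5)), sim$cohort)
  rep2 <- check_positivity(sim$cohort, risks2, decision_rule(0.3, "A", "B"),
                           q_model_spec("x"))
  expect_false(any(rep2$flag))

  # cutoff 0: the low stratum is empty, reported as size 0 and unflagged
  rep3 <- check_positivity(sim$cohort, risks2, decision_rule(0, "A", "B"),
                           q_model_spec("x"))
  low3 <- rep3[rep3$stratum == "low" & rep3$covariate == "(stratum)", ]
  expect_equal(low3$n_cell, 0L)
  expect_false(low3$flag)
})

test_that("missing covariate values are an error, not silently imputed", {
  toy <- toy_cohort()
  toy$x[3] <- NA
  expect_error(fit_q_model(toy, q_model_spec("x")), "imputation")
})
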