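# Split-sample orchestration: train the prognostic model, optimize the
# rule, validate its clinical utility — each on its own partition so the
# final emulated trial evaluates a specific, fixed decision rule in an
# independent sample.

#' Split plan for the three-stage workflow
#'
#' @param fractions numeric vector `(train, optimize, validate)` summing to
#'   1; an entry may be 0 when that stage's input is supplied externally
#'   (e.g. a published prognostic model).
#' @param seed integer seed for the random partition.
#' @param mode `"three-way"` (fit model, optimize rule, validate),
#'   `"two-way-rule-given"` (risk model external; optimize + validate) or
#'   `"validate-only"` (model and rule external; all data validates).
#' @return object of class `split_plan`.
#' @export
split_plan <- function(fractions = c(1, 1, 1) / 3, seed = 1L,
                       mode = c("three-way", "two-way-rule-given",
                                "validate-only")) {
  mode <- match.arg(mode)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-12) {
    stopf("fractions must be three non-negative numbers summing to 1")
  }
  need_zero <- switch(mode,
    "three-way" = integer(0),
    "two-way-rule-given" = 1L,
    "validate-only" = 1:2)
  if (any(fractions[need_zero] > 0)) {
    stopf("mode '%s' requires fraction(s) %s to be zero",
          mode, paste(need_zero, collapse = ", "))
  }
  structure(list(fractions = fractions, seed = as.integer(seed), mode = mode),
            class = "split_plan")
}

#' Randomly split a cohort into train / optimize / validate partitions
#'
#' A seeded permutation partitions the rows disjointly and exhaustively.
#' Partition sizes are the floors of `n * fraction` for the train and
#' optimize partitions; the remainder goes to the validation partition,
#' which carries the final evidentiary weight.
#'
#' @param cohort cohort data frame.
#' @param plan a [split_plan()].
#' @return named list of data frames `train`, `optimize`, `validate`.
#' @export
split_sample <- function(cohort, plan) {
  stopifnot(inherits(plan, "split_plan"))
  n <- nrow(cohort)
  if (!n) stopf("cannot split an empty cohort")
  perm <- with_stream(plan$seed, "split", sample.int(n))
  n_train <- floor(n * plan$fractions[1])
  n_opt <- floor(n * plan$fractions[2])
  idx_train <- perm[seq_len(n_train)]
  idx_opt <- perm[n_train + seq_len(n_opt)]
  idx_val <- perm[setdiff(seq_len(n), seq_len(n_train + n_opt))]
  list(train = cohort[sort(idx_train), , drop = FALSE],
       optimize = cohort[sort(idx_opt), , drop = FALSE],
       validate = cohort[sort(idx_val), , drop = FALSE])
}

read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

config_sim <- function(cfg) {
  s <- cfg$simulation
  covs <- lapply(s$covariates, function(cv) cv)
  ei <- NULL
  if (!is.null(s$effect_interaction)) {
    ei <- setNames(as.numeric(s$effect_interaction$value),
                   s$effect_interaction$covariate)
  }
  sim_config(
    n_subjects = s$n_subjects,
    covariates = covs,
    risk_coefficients = as.numeric(unlist(s$risk_coefficients)),
    treatment_effect = s$treatment_effect %||% 0,
    effect_interaction = ei,
    confounding_coefficients = as.numeric(unlist(s$confounding_coefficients)),
    grace_period_days = s$grace_period_days %||% 14L,
    horizon_days = s$horizon_days %||% 1826L,
    treatments = as.character(unlist(s$treatments %||% c("A", "B"))),
    seed = cfg$seed
  )
}

#' Run the full emulation pipeline from a configuration file
#'
#' Executes, in order: simulate-or-load the cohort, apply eligibility,
#' split the sample, fit (or load) the prognostic risk model on the
#' training partition, choose the cutoff and optimize the rule on the
#' optimization partition, and estimate the intention-to-treat contrast
#' with bootstrap inference on the untouched validation partition. Every
#' stage logs its seed and counts; a stage failure halts with the stage
#' name.
#'
#' The configuration is a structured YAML file with blocks `simulation`
#' (or `cohort_file`), `risk_model` (`covariates`, optionally `file` for an
#' external model), `cutoff` (`high_risk_fraction` or `risk_threshold`),
#' `rules` (`cutoff_grid`, `constraints`, optionally `file` for an external
#' rule), `q_model` (`covariates`, `interactions`), `eligibility`
#' (`criteria`, `grace_period_days`, `horizon_days`), `split` (`fractions`,
#' `mode`), `bootstrap` (`n_boot`, `level`) and `seed`.
#'
#' @param config path to the YAML configuration file, or an equivalent
#'   nested list.
#' @param out optional directory; when given, the cohort, the fitted risk
#'   model, the selected rule, the score table, a key-value result file and
#'   a human-readable report are written there.
#' @param seed optional integer overriding the configuration seed.
#' @param quiet suppress progress messages.
#' @return object of class `pipeline_result`: the [estimate_delta()] fit,
#'   the risk model, the selected rule, the optimization score table, the
#'   split sizes and the configuration used.
#' @export
run_pipeline <- function(config, out = NULL, seed = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # --- stage 1: obtain the cohort -----------------------------------------
  sim <- NULL
  cohort <- stage("cohort", {
    if (!is.null(cfg$cohort_file)) {
      say("stage cohort: reading %s", cfg$cohort_file)
      read_cohort(cfg$cohort_file)
    } else {
      scfg <- config_sim(cfg)
      say("stage cohort: simulating n = %d (seed %d)", scfg$n_subjects, scfg$seed)
      sim <- simulate_cohort(scfg)
      sim$cohort
    }
  })

  # --- stage 2: eligibility ------------------------------------------------
  el <- cfg$eligibility %||% list()
  crit <- unlist(el$criteria) %||% character(0)
  espec <- eligibility_spec(crit,
                            grace_period_days = el$grace_period_days %||% 14L,
                            horizon_days = el$horizon_days %||% 1826L)
  eligible <- stage("eligibility", apply_eligibility(cohort, espec))
  say("stage eligibility: %d of %d subjects eligible", nrow(eligible), nrow(cohort))

  # --- stage 3: split ------------------------------------------------------
  sp <- cfg$split %||% list()
  fr <- if (is.null(sp$fractions)) rep(1, 3) / 3 else
    as.numeric(unlist(sp$fractions))
  plan <- split_plan(fr, seed = cfg$seed, mode = sp$mode %||% "three-way")
  parts <- stage("split", split_sample(eligible, plan))
  say("stage split (%s): train %d / optimize %d / validate %d", plan$mode,
      nrow(parts$train), nrow(parts$optimize), nrow(parts$validate))

  # --- stage 4: prognostic model ------------------------------------------
  rm_cfg <- cfg$risk_model %||% list()
  risk_mod <- stage("risk-model", {
    if (!is.null(rm_cfg$file)) {
      say("stage risk-model: external model from %s", rm_cfg$file)
      read_risk_model(rm_cfg$file)
    } else if (!is.null(rm_cfg$coefficients)) {
      say("stage risk-model: external coefficients from config")
      risk_model(as.character(unlist(rm_cfg$covariates)),
                 as.numeric(unlist(rm_cfg$coefficients)))
    } else {
      say("stage risk-model: fitting on training partition")
      fit_risk_model(parts$train, as.character(unlist(rm_cfg$covariates)))
    }
  })

  # --- stage 5: cutoff and rule optimization ------------------------------
  space <- action_space(as.character(unlist(cfg$action_space %||% c("A", "B"))))
  qcfg <- cfg$q_model %||% list()
  qspec <- q_model_spec(as.character(unlist(qcfg$covariates) %||% character(0)),
                        as.character(unlist(qcfg$interactions) %||% character(0)))
  rcfg <- cfg$rules %||% list()
  opt <- NULL
  rule <- stage("optimize-rule", {
    if (!is.null(rcfg$file)) {
      say("stage optimize-rule: external rule from %s", rcfg$file)
      read_rules(rcfg$file)[[1]]
    } else if (!is.null(rcfg$cutoff) && !is.null(rcfg$low)) {
      say("stage optimize-rule: fixed rule from config")
      decision_rule(rcfg$cutoff, rcfg$low, rcfg$high, space)
    } else {
      opt_cohort <- parts$optimize
      opt_risks <- predict(risk_mod, opt_cohort)
      grid <- as.numeric(unlist(rcfg$cutoff_grid %||% NULL))
      if (!length(grid)) {
        cut_cfg <- cfg$cutoff %||% list(high_risk_fraction = 0.25)
        curve <- predictiveness_curve(opt_risks, opt_cohort$outcome)
        grid <- select_cutoff(curve,
                              high_risk_fraction = cut_cfg$high_risk_fraction,
                              risk_threshold = cut_cfg$risk_threshold)
        say("stage optimize-rule: predictiveness-curve cutoff %.4f", grid)
      }
      constraints <- NULL
      if (length(rcfg$constraints)) {
        constraints <- rule_constraint(
          lapply(rcfg$constraints, function(fb) c(fb$stratum, fb$treatment)),
          space)
      }
      cands <- enumerate_rules(space, grid, constraints)
      say("stage optimize-rule: scoring %d candidates on n = %d",
          length(cands), nrow(opt_cohort))
      opt <- optimize_rule(cands, opt_cohort, opt_risks, qspec, espec)
      opt$best
    }
  })
  say("stage optimize-rule: selected %s", format(rule))

  # --- stage 6: validate ---------------------------------------------------
  bcfg <- cfg$bootstrap %||% list()
  fit <- stage("validate", {
    val <- parts$validate
    risks_val <- predict(risk_mod, val)
    estimate_delta(val, risks_val, rule, qspec, espec,
                   n_boot = bcfg$n_boot %||% 200L,
                   level = bcfg$level %||% 0.95,
                   boot_seed = cfg$seed)
  })
  say("stage validate: Delta = %+.4f on n = %d", fit$delta, fit$n_eligible)

  res <- structure(
    list(fit = fit, risk_model = risk_mod, rule = rule,
         scores = if (!is.null(opt)) opt$scores,
         split_sizes = vapply(parts, nrow, 0L),
         exclusions = attr(eligible, "exclusions"),
         external = c(risk_model = !is.null(rm_cfg$file) ||
                        !is.null(rm_cfg$coefficients),
                      rule = !is.null(rcfg$file) ||
                        (!is.null(rcfg$cutoff) && !is.null(rcfg$low))),
         config = cfg, sim = sim),
    class = "pipeline_result")
  if (!is.null(out)) write_pipeline_result(res, out)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Emulated-trial pipeline",
      sprintf("(%s split: %s)\n", x$config$split$mode %||% "three-way",
              paste(x$split_sizes, collapse = " / ")))
  if (any(x$external)) {
    cat("  externally supplied:",
        paste(names(x$external)[x$external], collapse = ", "), "\n")
  }
  print(x$fit)
  invisible(x)
}

#' Write a pipeline result to disk
#'
#' Emits a key-value machine-readable result file, a plain-text report,
#' the fitted risk model, the selected rule, and the candidate score table.
#'
#' @param res a `pipeline_result`.
#' @param dir output directory (created if absent).
#' @export
write_pipeline_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fit <- res$fit
  kv <- list(mean_pred_arm = fit$mean_pred_arm, mean_soc_arm = fit$mean_soc_arm,
             delta = fit$delta, n_eligible = fit$n_eligible,
             n_early = fit$n_early, seed = res$config$seed,
             rule = format(res$rule),
             split_sizes = as.list(res$split_sizes))
  if (!is.null(fit$bootstrap)) {
    kv$ci_lower <- fit$bootstrap$ci_lower
    kv$ci_upper <- fit$bootstrap$ci_upper
    kv$n_boot <- fit$bootstrap$n_boot
    kv$n_failed <- fit$bootstrap$n_failed
  }
  yaml::write_yaml(kv, file.path(dir, "result.yaml"), precision = 12L)
  write_risk_model(res$risk_model, file.path(dir, "risk_model.yaml"))
  write_rules(res$rule, file.path(dir, "rule.yaml"))
  if (!is.null(res$scores)) {
    utils::write.csv(res$scores, file.path(dir, "rule_scores.csv"),
                     row.names = FALSE)
  }
  rep_path <- file.path(dir, "report.txt")
  con <- file(rep_path, "w")
  sink(con)
  on.exit({ sink(); close(con) })
  cat("Emulated target trial report\n============================\n\n")
  cat("Configuration seed:", res$config$seed, "\n")
  if (!is.null(res$exclusions) && length(res$exclusions)) {
    cat("Eligibility exclusions:\n")
    for (nm in names(res$exclusions)) {
      cat(sprintf("  %s: %d excluded\n", nm, res$exclusions[[nm]]))
    }
  }
  cat("\n")
  print(res)
  cat("\n")
  print(summary(res$fit))
  invisible(res)
}
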