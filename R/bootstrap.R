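# Nonparametric bootstrap for the intention-to-treat contrast.
#
# The same subjects appear in both arms of the emulated trial (everyone is
# in the standard-of-care arm; eligible subjects also feed the rule arm),
# so the two arm estimates are dependent and a per-arm variance would be
# wrong. Resampling whole subjects from the eligible cohort and re-running
# the entire estimation pipeline per replicate carries that dependence into
# the variance estimate.

#' Bootstrap confidence interval for Delta
#'
#' Resamples subjects with replacement from the full eligible cohort (never
#' per-arm), recomputes the complete pipeline — risk strata, Q-model fits,
#' both arm means, their difference — for each replicate via the very same
#' [estimate_delta()] code path used for the point estimate, and forms a
#' percentile interval. Replicates in which a stratum loses positivity (or
#' a Q model cannot be fitted) are dropped and counted in `n_failed`;
#' if more than 20% fail the cohort is too small or the Q model too rich
#' for reliable inference and an error is raised.
#'
#' @inheritParams estimate_rule_mean
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed integer seed; the replicate stream is reproducible given it.
#' @param level confidence level of the percentile interval.
#' @return object of class `boot_delta`: `point_estimate`, `replicates`
#'   (successful Delta* values), `ci_lower`, `ci_upper`, `level`, `n_boot`,
#'   `n_failed`, `seed`.
#' @export
bootstrap_delta <- function(cohort, risks, rule, q_spec,
                            spec = eligibility_spec(),
                            n_boot = 200L, seed = 1L, level = 0.95) {
  if (n_boot < 2L) stopf("n_boot must be at least 2")
  if (level <= 0 || level >= 1) stopf("level must lie in (0, 1)")
  n <- nrow(cohort)
  if (length(risks) != n) {
    stopf("risks (%d) not aligned with cohort rows (%d)", length(risks), n)
  }
  point <- estimate_delta(cohort, risks, rule, q_spec, spec)
  reps <- numeric(0)
  n_failed <- 0L
  with_stream(seed, "bootstrap", {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot_cohort <- cohort[idx, , drop = FALSE]
      boot_cohort$id <- sprintf("B%07d", seq_len(n))   # resampled rows are distinct subjects
      est <- tryCatch(
        estimate_delta(boot_cohort, risks[idx], rule, q_spec, spec,
                       diagnostics = FALSE),
        error = function(e) e
      )
      if (inherits(est, "error")) n_failed <- n_failed + 1L
      else reps[length(reps) + 1L] <- est$delta
    }
  })
  if (n_failed / n_boot > 0.2) {
    stopf(paste("%d of %d bootstrap replicates failed positivity;",
                "use a larger sample or a coarser Q model"),
          n_failed, n_boot)
  }
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
  structure(list(point_estimate = point$delta, replicates = reps,
                 ci_lower = ci[1], ci_upper = ci[2], level = level,
                 n_boot = as.integer(n_boot), n_failed = n_failed,
                 seed = as.integer(seed)),
            class = "boot_delta")
}

#' @export
print.boot_delta <- function(x, digits = 4, ...) {
  cat(sprintf("Nonparametric bootstrap for Delta (%d replicates, %d failed)\n",
              x$n_boot, x$n_failed))
  cat(sprintf("  point estimate: %+.*f\n", digits, x$point_estimate))
  cat(sprintf("  %d%% percentile CI: [%+.*f, %+.*f]\n",
              round(100 * x$level), digits, x$ci_lower, digits, x$ci_upper))
  invisible(x)
}

#' Dump bootstrap replicates as one-column delimited text
#'
#' @param boot a [bootstrap_delta()] result.
#' @param path file path.
#' @export
write_replicates <- function(boot, path) {
  utils::write.csv(data.frame(delta = boot$replicates), path, row.names = FALSE)
  invisible(path)
}
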