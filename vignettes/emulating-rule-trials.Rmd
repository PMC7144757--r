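---
title: "Emulating a target trial of a prediction-based treatment rule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a target trial of a prediction-based treatment rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruletrial)
```

## The estimand and the emulation

A prediction-based decision rule maps a prognostic risk score to a
treatment in a small action space — here two options, `A` (monotherapy)
and `B` (combination therapy) — through a single cutoff `c`: patients with
predicted risk at or above `c` are "high risk" and receive the high-stratum
treatment, everyone else the low-stratum treatment. The question of
clinical utility is whether deploying that rule would reduce the
proportion of patients with the adverse outcome `Y` within a fixed horizon
(default 1826 days, five years) relative to the standard of care. The
target trial randomizes eligible patients at time zero (diagnosis) to
rule-guided care or standard care; its intention-to-treat estimand is

$$\Delta \;=\; E[Y^{\text{pred}}] - E[Y^{\text{soc}}],$$

negative values favouring the rule.

In observational data the standard-of-care arm needs no modelling at all:
the observed eligible population received standard care, so
$E[Y^{\text{soc}}]$ is estimated by the plain event proportion over
*everyone* eligible (`estimate_soc_mean()`). The rule arm is reconstructed
from the decomposition

$$E[Y^{\text{pred}}] \;=\; P(\text{low})\,E[Y^{a_{\text{low}}}\mid\text{low}]
  \;+\; P(\text{high})\,E[Y^{a_{\text{high}}}\mid\text{high}],$$

with stratum proportions estimated empirically and each conditional
potential-outcome mean estimated by g-computation
(`estimate_rule_mean()`): within the stratum, fit the Q model
$E[Y \mid T, X]$ — logistic in a treatment indicator and the declared
confounders, with optional treatment-by-covariate interactions — then
predict every subject's outcome with treatment *set* to the rule's
assignment and average the predictions. Q models are fitted separately per
stratum; this is the saturated-in-stratum default and costs little when
strata are large. Identification rests on the usual three conditions:
positivity of the assigned treatment within every covariate pattern of the
stratum (diagnosed by `check_positivity()`, which bins continuous
confounders into deciles and flags cells with fewer than 5 subjects on the
assigned treatment), no unmeasured confounding given the Q-model
covariates, and correct specification of the Q model.

### The grace period

Treatment rarely starts on the day eligibility is met. The emulation
allows a grace period (default 14 days) between time zero and treatment
start, and any subject whose event occurs within it cannot meaningfully be
assigned to either strategy — conditioning on surviving to treatment start
would select survivors into the arms. Such early-event subjects are
therefore counted in **both** arms with their factual outcome of 1: in the
standard-of-care arm automatically (it averages everyone), and in the rule
arm by contributing 1 to their risk stratum's mean with ordinary $1/n$
weight while being excluded from Q-model fitting, where their treatment
may be undefined. The boundary is inclusive (an event exactly at the
grace-period day is "early"), a convention fixed package-wide and tested.
Whether early events should instead be down-weighted or handled by cloning
and censoring weights is a genuinely open design point; the $1/n$-in-both-
arms choice is the simplest reading consistent with avoiding survivor
bias, and both arms share the same eligibility and early-event
construction so the contrast is internally consistent.

### Inference

Because every subject feeds the SOC mean and the eligible subjects also
feed the rule arm, the two arm estimates are strongly dependent, and a
per-arm variance would be wrong. `bootstrap_delta()` therefore resamples
*whole subjects* with replacement from the eligible cohort and reruns the
entire pipeline — stratification, Q fits, both arms, Δ — per replicate,
through literally the same `estimate_delta()` code path as the point
estimate (only the positivity diagnostics are skipped for speed; they do
not enter the estimate). The default interval is the percentile interval:
assumption-light, exactly testable in degenerate cases (a cohort with no
events yields width zero), and adequate at the cohort sizes the package
targets. Replicates that lose positivity in some stratum are dropped and
counted rather than retried — retrying would tilt the bootstrap
distribution toward positivity-rich configurations — and more than 20%
failures is an error suggesting a larger sample or coarser Q model.

## Developing the rule

`predictiveness_curve()` summarises the distribution of predicted risk:
for each grid point $p$ it reports the empirical $p$-quantile of the risks
(the predictiveness curve $R(p)$) and, as a companion diagnostic, the
observed event rate among subjects above that quantile. `select_cutoff()`
turns it into a cutoff either by fixing the fraction labelled high risk
(the $1-q$ quantile of the risks) or by an absolute risk threshold.
Quantiles use the standard interpolating empirical quantile
(`stats::quantile`, type 7), the single convention applied everywhere in
the package so hand-checkable toy examples are stable; the stratum
boundary is closed on the high side (risk ≥ cutoff is high risk), since
some tie rule must be fixed and escalating at the boundary is the cautious
reading.

`enumerate_rules()` builds the candidate set (cutoff grid × stratum
assignments), prunes expert-opinion constraints such as "`B` must not be
given to low-risk patients", and keeps the constant treat-everyone rules
once each (at cutoff 1) so the obvious baselines are always scored.
`optimize_rule()` scores each candidate with the *same* g-computation
estimator used at validation — using a different estimator for
optimization than for validation would optimize the wrong objective — and
minimizes a pluggable scalar utility of the estimated event proportion,
by default the proportion itself. Ties break toward the larger cutoff
(fewer patients escalated, a least-intervention preference) and then
alphabetically on the assignment.

## The split-sample workflow

`split_sample()` partitions the eligible cohort by a seeded permutation
into training (prognostic model), optimization (rule choice) and
validation (emulated trial) sets; sizes are floors of the fractions with
the remainder assigned to validation, which carries the final evidentiary
weight. Either of the first two stages can be replaced by external
information (a published risk model, a pre-specified rule), shrinking the
split to two-way or validate-only; `run_pipeline()` exposes all three
modes from one configuration file and never touches the validation
partition before the final stage (a property asserted behaviourally in the
test suite: corrupting validation outcomes must leave the fitted model and
the selected rule bit-identical). Because the validated rule is fixed
before the validation data are seen, the bootstrap does not re-run rule
optimization inside replicates.

## The simulator and what passing tests mean

`simulate_cohort()` emulates a register of newly diagnosed patients:
covariates from declared families, treatment assignment from a logistic
model on covariates (the confounding mechanism), and a binary event within
the horizon from a logistic risk model with a log-odds treatment effect,
optionally interacted with one covariate to create qualitative
interactions. Both potential outcomes are drawn from a *single shared
uniform* per subject, so individual effects are monotone, a zero effect
gives identical potential outcomes subject by subject, and
`true_rule_value()` is an exact oracle for any rule's arm mean. Event
times are uniform on the horizon and treatment start times uniform on the
grace window — only the "event within grace period" indicator matters
downstream, so no real-world delay law is asserted. Each logical draw uses
its own seeded substream, so adding a covariate never perturbs the
assignment or outcome draws.

Four fixed benchmark scenarios (`scenario_confounded()`,
`scenario_null()`, `scenario_interaction()`, `scenario_beneficial()`)
define the package's validation conditions, all with realistic ~20%
five-year event risks. In the confounded scenario the prognostic score
uses only `x1` while a binary `x2` both raises risk (log-odds 1.9) and
strongly selects into combination therapy (log-odds 3): confounding then
operates *within* risk strata — the situation the Q-model adjustment
exists for — and the treatment-only estimator is measurably biased
(about −0.026) while the adjusted one is not. The interaction scenario
makes the benefit of `B` cross zero exactly at baseline risk 0.3, so a
0.3 cutoff is truly optimal by construction. The validation suite checks,
at the sizes it states (50 cohorts of 200 for the standardization
identity; 200 replicates of 5000 for bias; 200 cohorts of 2000 with 200
bootstrap replicates for coverage; 100 replicates of 5000 for optimizer
recovery; 1000 fuzzed cohorts for the grace-period invariants), that the
estimators agree with brute-force standardization to 10⁻¹⁰, are unbiased
under a correct Q model, fix what the naive estimator gets wrong, cover
the oracle at near-nominal rates, and recover the optimal cutoff.

What passing does **not** show: the simulator draws covariates
independently, generates outcomes from the same family the Q model fits
(so Q-model misspecification in real data is not represented beyond the
deliberately naive estimator), has no censoring, no missing data, no
measurement error in the risk score's inputs, and no unmeasured
confounding. On real register data those threats are live; quantitative
bias analysis for unmeasured confounding is out of scope here, as are
inverse-probability weighting and doubly robust estimators — g-computation
with an explicit Q model is the single estimation strategy implemented.

## Numerical choices and degenerate inputs

Logistic fits use `stats::glm.fit` with a deviance tolerance of 1e-10 and
up to 200 iterations. Rank-deficient designs drop aliased columns (their
coefficients reported as zero); unconverged fits or runaway coefficients
(|β| > 25) raise a separation error naming the offending columns. A
subgroup with a constant outcome yields a degenerate fit predicting that
constant — this keeps bootstrap replicates of event-free cohorts exact —
while a subgroup that saw only one treatment with a varying outcome raises
a positivity error naming the stratum. Empty strata carry weight zero and
are skipped; a cohort consisting entirely of early events estimates a rule
arm mean of 1 without fitting anything. Missing confounder values are an
error, never imputed: silent imputation would corrupt the causal contract.
Subjects whose factual treatment lies outside the declared action space
stay in the SOC arm (it is the observed population) and receive
standardized predictions in the rule arm, but are excluded from Q fits.

## Limitations

The package evaluates one two-stratum deterministic rule at a time against
a binary fixed-horizon outcome; per-protocol effects, time-varying
treatment, survival outcomes with censoring, stochastic rules, more than
two risk strata and simultaneous inference over many candidate rules are
out of scope. The utility is a scalar function of the event proportion;
richer multi-attribute utilities can be plugged in only insofar as they
are functions of that proportion.
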