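Package: ruletrial
Title: Emulated Target Trials for Prediction-Based Treatment Decision Rules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to develop and evaluate the clinical utility of a
    prediction-based treatment decision rule using observational data, by
    emulating the randomized target trial that would compare rule-guided care
    against the standard of care. Provides per-stratum g-computation of
    potential-outcome means under a deterministic risk-cutoff rule, a plug-in
    standard-of-care arm, grace-period handling for events occurring before
    treatment start, predictiveness-curve cutoff selection, enumeration and
    optimization of candidate rules under expert constraints, nonparametric
    bootstrap inference for the intention-to-treat contrast, a split-sample
    workflow (train / optimize / validate), and a synthetic cohort simulator
    with known potential outcomes for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
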