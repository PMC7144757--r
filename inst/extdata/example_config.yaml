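# Example pipeline configuration: a simulated register with a prognostic
# covariate (x1) and a confounder (x2) that drives both combination-therapy
# prescribing and the event risk. Replace `simulation:` with
# `cohort_file: path.csv` to analyse real data.
seed: 42
simulation:
  n_subjects: 10000
  covariates:
    - name: x1
      dist: normal
      mean: 0.0
      sd: 1.0
    - name: x2
      dist: bernoulli
      prob: 0.5
  risk_coefficients: [-2.4, 0.9, 1.9]
  treatment_effect: -0.8
  confounding_coefficients: [-1.5, 0.0, 3.0]
  grace_period_days: 14
  horizon_days: 1826
eligibility:
  grace_period_days: 14
  horizon_days: 1826
split:
  fractions: [0.4, 0.3, 0.3]
  mode: three-way
risk_model:
  covariates: [x1]
rules:
  cutoff_grid: [0.2, 0.3, 0.4]
  constraints:
    - stratum: low
      treatment: B
q_model:
  covariates: [x1, x2]
bootstrap:
  n_boot: 200
  level: 0.95
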