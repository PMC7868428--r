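# Quick-mode comparative study of the five single-prior estimators.
# reps is far below the 20000 default, so Monte Carlo standard errors are
# wide; intended for smoke runs.
population:
  icc_x: 0.1
  beta_b: 0.7
  beta_w: 0.2
  tau2_y: 0.15
study:
  type: figure1
  n: 5
  J_grid: [20, 40, 60]
  reps: 200
  nu0: [1.0]
  seed: 1
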