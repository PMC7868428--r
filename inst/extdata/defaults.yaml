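# Default study conditions for the comparative RMSE studies.
# Standardized variables (unit total variance at Level 1); the group-level
# residual variance of the outcome (tau2_y) and the within-group slope
# (beta_w) are not separately varied by the studies.
population:
  icc_x: 0.1
  beta_b: 0.7
  beta_w: 0.2
  tau2_y: 0.15
study:
  n: 5
  J_grid: [20, 30, 40, 50, 60]
  reps: 20000
  nu0: [0.1, 1.0, 5.0]
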