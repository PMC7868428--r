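# Worked prior translation: slightly informative priors with prior sample
# size 1, slope guess 0, variance guess 1, evaluated at sample variance
# estimates tau2_y_hat = 0.15 and tau2_x_hat = 0.1.
priors:
  direct:
    beta0: 0
    nu0: 1
  indirect:
    tau0_sq: 1
    nu0: 1
estimates:
  tau2_y: 0.15
  tau2_x: 0.1
labels:
  slope: "slope"
  variance: "variance"
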