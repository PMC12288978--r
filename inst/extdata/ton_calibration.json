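{
  "slope": 2.697,
  "intercept": -2.445,
  "slope_ci": [2.13, 3.265],
  "intercept_ci": [-11, 6.11],
  "sigma": null,
  "r2": 0.87,
  "n_fit": null
}
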