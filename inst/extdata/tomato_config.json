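{
  "delta": 0.6,
  "positional_weights": [0.200, 0.180, 0.170, 0.150, 0.130, 0.100, 0.020, 0.010, 0.010, 0.010, 0.010, 0.010],
  "probabilities": [0.057, 0.038, 0.057, 0.189, 0.151, 0.132, 0.094, 0.057, 0.075, 0.038, 0.019, 0.094],
  "confidences": [0.200, 0.300, 0.300, 0.300, 0.100, 0.400, 0.500, 0.200, 0.800, 0.500, 0.700, 1.000],
  "criterion_weights": [0.089, 0.090, 0.236, 0.274, 0.079, 0.110, 0.122],
  "mean_mode": "plain",
  "sd_ordering": "magnitude",
  "case": 1,
  "zero_variance": "error",
  "renormalize": true
}
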