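# Example cohort pipeline configuration
n_response: 6
n_progression: 2
seed: 1
n_standard: 1000
cluster_mode: 2d
cluster_scope: subset
thresholds:
  suv_cut: 2.5
  adc_cut: 1250
  adc_outlier: 50
phantom:
  grid_shape: [48, 48, 16]
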