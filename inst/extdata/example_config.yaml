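# Example analysis configuration consumed by read_config()
protocol: imaging3_component
seed: 1
rate_hz: 2
kernel_tau_s: 3.5
theta: 1.0
cohort:
  n_fish: 11
  rois_per_fish: 500
  amplitude: 3
  noise_sd: 1
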