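# Example simulated-study configuration (see ?study_config_from_yaml)
n_specimens: 7
seed: 42
imaging: true
spacing: 1.5
soft_margin: 30
swap_phase_labels: false
template:
  resting_gap: 39.9
  target_total_length: 310.0
joints:
  isld_flexion_multiplier: 1.639650
hu:
  bone_mean: 1500
  bone_sd: 150
  soft_tissue_mean: 40
  soft_tissue_sd: 30
  noise_sd: 20
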