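# Demo pipeline configuration: short runs of every stage.
seed: 42
tcc:
  duration_s: 300
  tau_tcc_s: 3
  noise_sd_nm: 8
  min_step_nm: 24
relaxation:
  tau_apic_s: 20
  rebind_prob: 0.5
  total_turns: 25
  noise_sd_nm: 8
force_jump:
  tau0_days: 245
  delta_x_nm: 0.89
  forces_pN: [30, 40, 50]
  n_per_force: 40
  temperature_K: 298
kinetics:
  noise_sd: 0.03
  replicates: 3
  n_starts: 3
afm:
  n_oc: 500
  n_sc: 500
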