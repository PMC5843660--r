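# Example dgnet configuration: the reference epileptogenesis experiment
# at reduced horizon. All fields are optional; package defaults apply.
network:
  n_gc: 100
  n_mc: 3
  n_in_a: 2
  n_in_b: 1
  nu: 0.1
  rho: 0.3
ns:
  a_e: 1.0
  a_i: 0.05
  tau_i: 120
protocol:
  stim_start: 1.5
  stim_duration_min: 70
  alpha: 1.0
  t_i: 2.0
  gabaa_duration_days: 14
  inverted_fraction: 0.25
  total_days: 30
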