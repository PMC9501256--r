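# Example magtrap run configuration.
mode: sweep
seed: 1
fluid:
  mean_velocity: 0.005        # m/s
  channel_height: 2.5e-4      # m
  channel_length: 2.0e-3      # m
magnet:
  B_edge: 0.3                 # T at the channel edge
  standoff_um: 100
  x_um: 1000
  pole_exponent: 2
sweep:
  cycles: [1, 2, 3]
  velocities_mm_s: [5, 10, 20, 50, 100]
  n_per_cell: 20
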