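# example workbench configuration
seed: 1
output_dir: petrv-out
bin_width_s: 10
energy_window:
  centre_keV: 511
  half_width: 0.10
  convention: half_width
plan:
  pitch_mm: 1.2
  dwell_time_s: 10
  current_nA: 6.0
  entry_energy: 7.5
  sigma_x_mm: 0.78
  sigma_y_mm: 0.89
  slab_um: 100
exvivo:
  scenario: T4
invivo:
  scenario: E1
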