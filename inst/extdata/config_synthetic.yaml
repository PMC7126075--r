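# fully synthetic end-to-end run: generate isotope + OTU data with known
# ground truth, then execute every stage with packaged default tables
seed: 1
n_perm: 199
simulate:
  enabled: true
  n_individuals: 6
  n_ceca: 5
  noise_sd: 0.5
policy:
  clip_order: before
  dbrda_direction: isotope_response
  axis_prop: 0.8
  separation_floor: 1.0
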