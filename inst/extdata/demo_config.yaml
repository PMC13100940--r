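# Demo: two simulated antibodies (strong and non-specific) against a
# secondary-only control, 4 fields per condition.
seed: 1
output_dir: srquant_demo
n_fields: 4
field:
  height_px: 192
  width_px: 192
  n_cells: 40
  positive_fraction: 0.4
conditions:
  - name: antibody_A
    dilution: "1:500"
    antibody_ratio: 3
  - name: antibody_B
    dilution: "1:500"
    antibody_ratio: 1
control:
  name: secondary_only
  antibody_ratio: 1
stats:
  min_negatives: 20
  conf_level: 0.95
  grade_t1: 0.5
  grade_t2: 2
power:
  run: false
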