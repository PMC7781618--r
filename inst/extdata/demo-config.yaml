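# Minimal demonstration run: two short-C-terminus constructs, small cohorts.
seed: 7
output_dir: cavgating-demo
protocols:
  use: [iv, ssi]
  iv_step_duration: 20
  dt: 0.1
preprocess:
  ljp: 0
  leak: offline
comparisons: reference
reference: 8b-43S
cohorts:
  - construct: 8b-43S
    n_cells: 4
  - construct: 8b-11-43S
    n_cells: 4
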