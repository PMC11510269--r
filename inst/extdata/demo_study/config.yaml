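# Demo run configuration for the bundled synthetic study (seed 42):
# one exposure, one mediator, one binary outcome.
seed: 42
output_dir: mr_output
traits:
  exposure:
    file: exposure.tsv
    type: continuous
  mediator:
    file: mediator.tsv
    type: continuous
  outcome:
    file: outcome.tsv
    type: binary
exposures: [exposure]
mediators: [mediator]
outcomes: [outcome]
run_presso: true
settings:
  p_instrument: 5.0e-8
  r2_max: 0.001
  window_kb: 10000
  f_min: 10
  n_boot: 1000
  presso_n_sim: 1000
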