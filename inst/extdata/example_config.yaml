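# Example pipeline configuration. Omitted keys take package defaults.
locus:
  mutation_len: 59
  intercut_mutant: 87
  amplicon_len: 670
  mha_len: 20
tolerances:
  max_sub_frac: 0.01
  cut_window: 10
  min_aav_match: 20
detection:
  slope: 0.528
  intercept: -0.154
rod_fraction: 0.75
seed: 1
sample: mmej_1m
inputs:
  fixture: mmej_1m
  error_rate: 0
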