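# Default batch-culture run of the integrated E. coli carbohydrate model.
# Parameters and thresholds omitted here fall back to the package defaults
# (default_parameters(), regulation_thresholds()).
model: ecoli
simulation:
  t_end: 13.5
  dt: 0.001
  record_stride: 0.02
seed: 1
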