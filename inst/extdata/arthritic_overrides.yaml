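# Example disease-state property overrides: a turbid, mildly absorbing
# synovial effusion and a hypervascular (more absorbing) synovial membrane.
# Illustrative template values, not measured pathology.
- tissue_id: 12
  field: mu_s
  factor: 5
- tissue_id: 12
  field: mu_a
  factor: 2
- tissue_id: 13
  field: mu_a
  factor: 1.5
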