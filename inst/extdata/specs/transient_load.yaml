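name: transient_load
seed: 4
parameters:
  amp: 4.9
  t0: 1.25
  width: 0.5
  n_steps: 5.0
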