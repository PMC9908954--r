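name: slip
seed: 7
parameters:
  t0: 1.5
  duration: 0.4
  n_steps: 5.0
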