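name: stepping_load
seed: 1
parameters:
  added_mass: 0.0
  n_steps: 20.0
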