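name: asterisk
seed: 3
parameters:
  force: 8.0
  dwell: 1.0
  transition: 0.25
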