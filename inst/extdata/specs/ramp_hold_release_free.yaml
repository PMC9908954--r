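name: ramp_hold_release_free
seed: 2
parameters:
  amp: 1.5
  ramp: 0.5
  hold: 2.0
  k_servo: 1.0
  t_pre: 0.5
  t_post: 2.0
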