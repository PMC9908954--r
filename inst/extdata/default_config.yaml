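cs_groups:
  6B:
    a: 338.9952
    b: 2.2707
    c: 7.1531
    d: -27.9311
    tau: 0.025
  6A:
    a: 338.9952
    b: 2.2707
    c: 7.1531
    d: -17.9311
    tau: 0.025
  '3':
    a: 338.9952
    b: 2.2707
    c: 7.1531
    d: -27.9311
    tau: 0.025
  '4':
    a: 338.9952
    b: 2.2707
    c: 7.1531
    d: -27.9311
    tau: 0.025
input_scales:
  tf: 820.0
  tib: 4190.0
leg:
  omega:
  - - 0.0
    - -0.601815
    - -0.7986355
  - - 1.0
    - 0.0
    - 0.0
  - - 1.0
    - 0.0
    - 0.0
  q:
  - - 0.0
    - 61.34
    - 15.03
  - - 0.0
    - 93.46
    - 22.36
  - - 0.0
    - 230.45
    - -80.9
  q_end:
  - 0.0
  - 362.42
  - -180.99
  scale: 15.0
footpath:
  step_period: 4.0
  treadmill_speed: 50.0
  duty: 0.75
  fs: 60.0
  x_touchdown: 0.0
  y_foot: 260.0
  z_ground: -170.0
  apex_height: 40.0
section:
  outer: 10.0
  wall: 1.0
  E: 2.4e+09
chain:
  fs: 60.0
  gain: 250.0
  adc_bits: 12.0
  vref: 3.3
  bridge_sens: 0.4
  noise_sd: 0.0016113
  drift_amp: 0.0040283
  drift_period: 60.0
  window: 13.0
gauge_frac: 0.1
poisson: 0.35
scaling:
  period_ratio: 6.0
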