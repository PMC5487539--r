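name: table1_nominal
description: Literature nominal constants with the package's documented nominal initial
  pressures.
params:
  R_e0: 0.016
  R_a: 0.06
  R_v0: 0.016
  R_LV: 1.2
  R_eM: 10.0
  C_e: 1.5
  C_a: 1.5
  C_v: 50.0
  E_d: 0.06
  E_s0: 3.0
  c1: 0.1
  c2: 6.0
  c3: 0.01
  c4: 500.0
  c5: 18.420680743952
  c6: 7.5
  omega0: 7.54
  phi: 0.333333333333
  eps1: 1.0e-05
  A1: 0.5
  dt0: 0.083331370122
  p_e0: 35.0
  p_a0: 35.0
  p_v0: 10.0
  p_LV0: 35.0
  V0: 0.0
expect: ~
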