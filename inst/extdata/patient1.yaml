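name: patient1
description: Normal pressures and heart rate; very small dicrotic notch; small respiratory
  variation.
params:
  R_e0: 0.0055222
  R_a: 0.020797
  R_v0: 0.0055259
  R_LV: 0.41279
  R_eM: 10.009
  C_e: 1.6946
  C_a: 2.0
  C_v: 15.0
  E_d: 0.065511
  E_s0: 0.57
  c1: 0.01
  c2: 4.0153
  c3: 0.00049874
  c4: 150.0
  c5: 18.445
  c6: 1.0
  omega0: 8.3706
  phi: 0.33334
  eps1: 1.0e-05
  A1: 0.40341
  dt0: 0.75786
  p_e0: 49.896
  p_a0: 55.0
  p_v0: 16.628
  p_LV0: 49.714
  V0: 0.0
expect:
  systolic: 120.0
  diastolic: 70.0
  hr: 79.0
  notch: yes
  resp_sys_variation: ~
  tol_pressure_frac: 0.1
  tol_hr_bpm: 2.0
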