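name: patient3
description: Normal pressures with a large dicrotic notch and ~5 mmHg respiratory
  systolic variation.
params:
  R_e0: 0.0049252
  R_a: 0.018469
  R_v0: 0.0049253
  R_LV: 0.39929
  R_eM: 10.004
  C_e: 1.54
  C_a: 1.0459
  C_v: 50.0
  E_d: 0.029022
  E_s0: 0.64627
  c1: 0.015
  c2: 4.0001
  c3: 0.0001251
  c4: 400.0
  c5: 1.0
  c6: 3.5
  omega0: 8.3339
  phi: 0.33338
  eps1: 1.0007e-05
  A1: 0.43995
  dt0: 0.75182
  p_e0: 21.783
  p_a0: 21.781
  p_v0: 7.2597
  p_LV0: 21.761
  V0: 0.0
expect:
  systolic: 135.0
  diastolic: 60.0
  hr: 80.0
  notch: yes
  resp_sys_variation: 5.0
  tol_pressure_frac: 0.1
  tol_hr_bpm: 2.0
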