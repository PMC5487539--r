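name: patient2
description: Haemorrhagic hypotension under vasoconstrictors; high heart rate; no
  dicrotic notch.
params:
  R_e0: 0.0038808
  R_a: 0.0154
  R_v0: 0.0038895
  R_LV: 0.29025
  R_eM: 10.116
  C_e: 2.9196
  C_a: 2.9193
  C_v: 55.456
  E_d: 0.0181
  E_s0: 0.34
  c1: 0.006
  c2: 7.003
  c3: 0.00010007
  c4: 7.7731e-06
  c5: 18.436
  c6: 4.5053
  omega0: 10.578
  phi: 0.33273
  eps1: 1.0049e-05
  A1: 0.4515
  dt0: 0.59617
  p_e0: 17.355
  p_a0: 17.355
  p_v0: 5.7844
  p_LV0: 17.355
  V0: 0.0
expect:
  systolic: 85.0
  diastolic: 45.0
  hr: 100.0
  notch: no
  resp_sys_variation: ~
  tol_pressure_frac: 0.1
  tol_hr_bpm: 2.0
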