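stages:
  egg:
    t_inf: 6.5
    t_sup: 32.0
    a: 3.000151378167e-05
  n1:
    t_inf: 3.0
    t_sup: 33.0
    a: 0.000149972206
  n2:
    t_inf: 3.0
    t_sup: 33.0
    a: 0.00010999221
  n3:
    t_inf: 2.1
    t_sup: 33.0
    a: 0.000132044272
  n4:
    t_inf: 3.0
    t_sup: 33.0
    a: 0.000149972206
  n5:
    t_inf: 3.0
    t_sup: 33.0
    a: 0.000100736998
diapause:
  t_e: 6.5
  dd_e: 120.0
age:
  alpha: 5.67
  beta: 1.05
n_eggs: 100.0
grid_cells: 200
cfl: 1.0
diffusivity: 0.0
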