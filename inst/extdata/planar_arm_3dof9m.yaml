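n_joints: 3
segment_length:
- 0.31
- 0.27000000000000002
- 0.14999999999999999
com_distance:
- 0.13500000000000001
- 0.12
- 0.06
mass:
- 1.95999999999999996
- 1.17999999999999994
- 0.45000000000000001
inertia:
- 0.0157
- 0.0072
- 0.0009
gravity:
- 0.0
- 0.0
q_ref:
- -0.39700000000000002
- 1.93500000000000005
- 0.0
q_range:
- - -1.0
  - 1.60000000000000009
- - 0.20000000000000001
  - 2.39999999999999991
- - -1.0
  - 1.0
task:
  segment: 3
  point:
  - 0.14999999999999999
  - 0.0
muscles:
- name: shoulder_flex
  fmax: 800.0
  path:
    seg:
    - 0
    - 0
    - 1
    - 1
    x:
    - -0.10000000000000001
    - -0.05
    - 0.05
    - 0.10000000000000001
    'y':
    - 0.04099999999999999
    - 0.036
    - 0.036
    - 0.031
- name: shoulder_ext
  fmax: 800.0
  path:
    seg:
    - 0
    - 0
    - 1
    - 1
    x:
    - -0.078
    - -0.028
    - 0.028
    - 0.078
    'y':
    - -0.042
    - -0.037
    - -0.037
    - -0.032
- name: elbow_flex
  fmax: 600.0
  path:
    seg:
    - 1
    - 1
    - 2
    - 2
    x:
    - 0.19500000000000001
    - 0.245
    - 0.065
    - 0.115
    'y':
    - 0.022
    - 0.017
    - 0.017
    - 0.012
- name: elbow_ext
  fmax: 600.0
  path:
    seg:
    - 1
    - 1
    - 2
    - 2
    x:
    - 0.252
    - 0.30199999999999999
    - 0.008
    - 0.058
    'y':
    - -0.043
    - -0.038
    - -0.038
    - -0.033
- name: wrist_flex
  fmax: 300.0
  path:
    seg:
    - 2
    - 2
    - 3
    - 3
    x:
    - 0.19
    - 0.24000000000000002
    - 0.03
    - 0.08
    'y':
    - 0.0171
    - 0.0121
    - 0.0121
    - 0.0071
- name: wrist_ext
  fmax: 300.0
  path:
    seg:
    - 2
    - 2
    - 3
    - 3
    x:
    - 0.21000000000000002
    - 0.26000000000000001
    - 0.01
    - 0.06
    'y':
    - -0.0298
    - -0.0248
    - -0.0248
    - -0.0198
- name: biart_sh_el_flex
  fmax: 700.0
  path:
    seg:
    - 0
    - 1
    - 1
    - 2
    x:
    - -0.055
    - 0.055
    - 0.23999999999999999
    - 0.07000000000000001
    'y':
    - 0.04
    - 0.04
    - 0.019
    - 0.019
- name: biart_el_wr_flex
  fmax: 400.0
  path:
    seg:
    - 1
    - 2
    - 2
    - 3
    x:
    - 0.25
    - 0.06
    - 0.24200000000000002
    - 0.028
    'y':
    - 0.016
    - 0.016
    - 0.0113
    - 0.0113
- name: biart_sh_el_ext
  fmax: 700.0
  path:
    seg:
    - 0
    - 1
    - 1
    - 2
    x:
    - -0.03
    - 0.03
    - 0.30099999999999999
    - 0.009
    'y':
    - -0.04
    - -0.04
    - -0.042
    - -0.042
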