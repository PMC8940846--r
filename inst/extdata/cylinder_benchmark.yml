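name: cylinder-benchmark-k0.05
geometry:
  type: cylinder
  radius: 10.0
  length: 90.0
  thickness: 1.41
  quarter: yes
  divisions:
  - 2.0
  - 15.0
  - 60.0
materials:
  single:
  - kind: matrix
    rho: 241.5
    mu: 72.0
    kappa: 7200.0
    lambda_h:
    - 1.25
    - 0.597014925373134
    - 1.34
  - kind: smc
    rho: 157.5
    k1: 7.6
    k2: 11.4
    angle: 0.0
    lambda_h: 1.1
    sigma_actmax: 54.0
    lambda_0: 0.8
    lambda_max: 1.4
    lambda_act: 1.0
    turnover: 101.0
  - kind: collagen
    rho: 65.099999999999994
    k1: 568.0
    k2: 11.199999999999999
    angle: 0.0
    lambda_h: 1.062
    turnover: 101.0
  - kind: collagen
    rho: 241.5
    k1: 568.0
    k2: 11.199999999999999
    angle: 0.785398163397448
    lambda_h: 1.062
    turnover: 101.0
  - kind: collagen
    rho: 241.5
    k1: 568.0
    k2: 11.199999999999999
    angle: -0.785398163397448
    lambda_h: 1.062
    turnover: 101.0
  - kind: collagen
    rho: 65.099999999999994
    k1: 568.0
    k2: 11.199999999999999
    angle: 1.570796326794897
    lambda_h: 1.062
    turnover: 101.0
pressure_mmHg: 100.0
boundary:
  k_pro: 0.0
  k_dis: 0.0
  radial_only: yes
insult:
  mode: insult
  D_max: 0.5
  L_dam: 10.0
  t_dam: 40.0
gain_frac: 0.05
horizon_days: 5475.0
dt_days: 10.0
prestretch:
  mode: as_given
output_every: 100.0
options: []
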