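name: toric-arch-k0.09-none
geometry:
  type: torus
  lumen_diameter: 36.0
  arch_radius: 65.0
  thickness: 2.38
  sweep_angle: 1.570796326794897
  layer_split: 0.5
  divisions:
  - 2.0
  - 16.0
  - 12.0
materials:
  media:
  - kind: matrix
    rho: 169.0
    mu: 80.0
    kappa: 3200.0
    lambda_h:
    - 1.3
    - 0.591715976331361
    - 1.3
  - kind: smc
    rho: 735.0
    k1: 13.800000000000001
    k2: 6.0
    angle: 0.0
    lambda_h: 1.1
    turnover: 101.0
  - kind: collagen
    rho: 14.6
    k1: 292.0
    k2: 5.6
    angle: 0.0
    lambda_h: 1.1
    turnover: 101.0
  - kind: collagen
    rho: 58.399999999999999
    k1: 292.0
    k2: 5.6
    angle: 0.785398163397448
    lambda_h: 1.1
    turnover: 101.0
  - kind: collagen
    rho: 58.399999999999999
    k1: 292.0
    k2: 5.6
    angle: -0.785398163397448
    lambda_h: 1.1
    turnover: 101.0
  - kind: collagen
    rho: 14.6
    k1: 292.0
    k2: 5.6
    angle: 1.570796326794897
    lambda_h: 1.1
    turnover: 101.0
  adventitia:
  - kind: matrix
    rho: 565.0
    mu: 80.0
    kappa: 3200.0
    lambda_h:
    - 1.3
    - 0.591715976331361
    - 1.3
  - kind: smc
    rho: 0.0
    k1: 13.800000000000001
    k2: 6.0
    angle: 0.0
    lambda_h: 1.1
    turnover: 101.0
  - kind: collagen
    rho: 48.5
    k1: 292.0
    k2: 5.6
    angle: 0.0
    lambda_h: 1.1
    turnover: 101.0
  - kind: collagen
    rho: 194.0
    k1: 292.0
    k2: 5.6
    angle: 0.785398163397448
    lambda_h: 1.1
    turnover: 101.0
  - kind: collagen
    rho: 194.0
    k1: 292.0
    k2: 5.6
    angle: -0.785398163397448
    lambda_h: 1.1
    turnover: 101.0
  - kind: collagen
    rho: 48.5
    k1: 292.0
    k2: 5.6
    angle: 1.570796326794897
    lambda_h: 1.1
    turnover: 101.0
pressure_mmHg: 80.0
boundary:
  k_pro: 1.0
  k_dis: 0.2
  radial_only: yes
insult:
  mode: none
  D_max: 0.5
  L_dam: 10.0
  t_dam: 40.0
gain_frac: 0.09
horizon_days: 0.0
dt_days: 10.0
prestretch:
  mode: calibrate
  lam_iv: 1.3
  eps_t: 3.0
  eps_d: 2.0
output_every: 100.0
options: []
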