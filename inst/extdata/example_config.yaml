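# Example pipeline configuration (units: nm, kJ/mol, ps, K)
system:
  kind: funnel_pocket_3d
  D: 20            # kJ/mol
  sigma_pocket: 0.3
  wall_stiffness: 1000
funnel:
  alpha: 0.35      # rad
  z_cc: 2.0
  R_cyl: 0.1
  z_wall: 5.5
  kappa_wall: 35100
  kappa_funnel: 35100
metad:
  h0: 2.0
  sigma_cv1: 0.1
  stride: 500
  gamma: 20
  grid_min: -0.3
  grid_max: 5.8
smd:
  preset: hold
walkers:
  n_walkers: 10
  from: 1.6
  spacing: 0.3
integrator:
  scheme: baoab
  dt: 0.001
  friction: 5
  temperature: 310
  n_steps: 6.0e6
  save_stride: 250
seeds:
  master: 1
output:
  dir: results
units:
  length: nm
  energy: kJ/mol
  time: ps
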