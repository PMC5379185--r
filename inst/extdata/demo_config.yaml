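# Demonstration pipeline configuration: a two-state synthetic switch loop
# analysed end to end at desk scale. Angles in degrees, distances in
# Angstrom, energies in kcal/mol, times in ps.
seed: 7
loop:
  n_res: 13
  kappa: 50
  weights: [0.6, 0.4]
  n_states: 2
  n_frames: 150
scv:
  form: half_cosine
  width_deg: 2.3
metad:
  delta_g: 2.0
  barrier: 4.0
  W: 0.1
  width: 0.1
  stride: 400
  bias_factor: 10
  kT: 0.5962
  dt: 0.005
  n_steps: 100000
  min_depth: 1.0
cluster:
  k: 4
  n_init: 10
hydration:
  density: 0.0334
  margin: 6.0
  cutoff: 4.0
  block_len: 10
energy:
  cutoff: 10.0
  n_frames: 40
  jitter: 0.05
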