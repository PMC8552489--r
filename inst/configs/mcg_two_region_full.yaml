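# Full-size counterpart of mcg_two_region.yaml: 1925-monomer NP with 12
# guests on a 40 x 40 nm two-region surface.
seed: 1
builder:
  model: mcg
  n_monomers: 1925
  n_guests: 12
  xy: [10, 20]
surface:
  lx: 40
  ly: 40
  rho_high: 1.0
  ratio: 0.015625
  receptor_model: monobead_frozen
pair_table:
  e_ass: 10
  e_bind: 40
metad:
  cv: com_xy
  group: np_beads
  height: 20
  width: 1.0
  stride: 5000
restraint:
  z0: 5
  kappa: 150
  exp: 2
  group: np_beads
output:
  steps: 2000000
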