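# Minimalistic NP exploring a two-region (64:1) receptor surface by
# metadynamics on the COM x/y position. `scale: desk` sizes run on a
# laptop; the full-size counterpart uses n_monomers: 1925 and lx: 40.
seed: 1
builder:
  model: mcg
  n_monomers: 200
  n_guests: 0
  xy: [3, 3]
surface:
  lx: 12
  ly: 6
  rho_high: 1.0
  ratio: 0.015625
  receptor_model: monobead_frozen
pair_table:
  e_ass: 10
  e_bind: 40
integrator:
  dt: 0.02
  temperature: 300
  gamma: 1.0
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
  steps: 200000
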