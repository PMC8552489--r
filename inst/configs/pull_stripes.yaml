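# Constant-force rolling over a receptor-density gradient (stripes
# 0 / 0.12 / 0.52 / 1.12 nm^-2). Desk scale: 16 oligomers, 8 x 8 nm
# stripes; the full-size run uses 44 oligomers and 30 x 30 nm stripes.
seed: 1
builder:
  model: fcg
  n_oligomers: 16
  n_charged_heads: 3
  n_guests: 6
  xy: [3, 3]
surface:
  stripe_densities: [0.0, 0.12, 0.52, 1.12]
  stripe_lx: 6
  ly: 6
  receptor_model: tribead_tethered
external_force:
  group: np_beads
  vector: [100, 0, 0]
restraint:
  z0: 5
  kappa: 150
  exp: 2
  group: np_beads
output:
  steps: 200000
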