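# Multiple-walker metadynamics preset (COM x/y bias, kernel height 1.2,
# width 0.1, stride 500) for gradient exploration; desk scale.
seed: 1
builder:
  model: fcg
  n_oligomers: 16
  n_charged_heads: 3
  n_guests: 0
  xy: [4, 4]
surface:
  stripe_densities: [0.0, 0.12, 0.52, 1.12]
  stripe_lx: 8
  ly: 8
  receptor_model: tribead_tethered
metad:
  cv: com_xy
  group: np_beads
  height: 1.2
  width: 0.1
  stride: 500
restraint:
  z0: 5
  kappa: 150
  exp: 2
  group: np_beads
output:
  steps: 100000
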