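# 44-oligomer trivalent micelle adhering to the densest uniform surface
# (rho4 = 1 receptor/nm^2, 20 x 20 nm, tethered three-bead receptors).
# rho1..rho3 counterparts use rho_high: 0.034 / 0.09 / 0.64.
seed: 1
builder:
  model: fcg
  n_oligomers: 44
  n_charged_heads: 3
  n_guests: 10
surface:
  lx: 20
  ly: 20
  rho_high: 1.0
  ratio: 1.0
  receptor_model: tribead_tethered
restraint:
  z0: 5
  kappa: 150
  exp: 2
  group: np_beads
output:
  steps: 500000
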