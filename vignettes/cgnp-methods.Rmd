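---
title: "Coarse-grained models of multivalent nanoparticle adhesion, rolling and release: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cgnp methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cgnp)
```

# The scientific problem

Supramolecular nanoparticles (NPs) built from self-assembling monomers can
bind surfaces displaying complementary receptors. When several
ligand–receptor pairs engage at once (multivalency), adhesion strength grows
super-additively, and an NP sitting on a receptor-density gradient
experiences a thermodynamic drive toward denser regions — a synthetic
analogue of chemotaxis. If the monomer–receptor binding well is much deeper
than the monomer–monomer self-assembly well, the surface can out-compete the
assembly itself: the NP deforms, exfoliates monomer layers, and releases
encapsulated guest molecules. `cgnp` implements coarse-grained (CG) models
and biased-sampling machinery to study this competition end to end: seeded
builders for NPs, receptor surfaces and counterions; a CG force field;
Langevin dynamics with center-of-mass (COM) pulling; metadynamics in
standard, well-tempered, multiple-walker and infrequent flavors; and the
observables (contacts, SASA, guest release, MSD, region occupancy) used to
quantify the behavior.

Units throughout: nm, ps, amu, kJ/mol, elementary charge e, kelvin.

# Models

## Minimalistic one-bead model (`mcg`)

Three bead types: monomers **M**, guests **G**, and surface receptors **R**
(single frozen beads in the surface plane). Interactions are LJ 12-6 pairs:

* M–M: sigma = 0.47 nm, eps = `e_ass` = 10 kJ/mol (the self-assembly well),
* M–R: sigma = 0.35 nm, eps = `e_bind` = 40 kJ/mol (the binding well),

so the default assembly/binding ratio is 1/4 — deep enough that receptor-rich
regions dominate the NP's fate. Guest interactions are not independently
parameterized in this resolution; they reuse the guest values of the finer
model (sigma = 0.43 nm, eps = 6.5 kJ/mol), weak enough that release is
promptly visible. Both well depths are exposed (`mcg_pair_table(e_ass,
e_bind)`) so the adhesion/disassembly crossover can be scanned.

## Generic oligomer (micelle) model (`fcg`)

A finer resolution in the MARTINI spirit (~4 heavy atoms per bead): each
oligomer is a branched amphiphile — one core bead, three hydrophobic
two-bead tails, and 1–3 charged head beads (−1 e each), giving oligomer
charges −1/−2/−3 e and, e.g., a 44-oligomer trivalent NP a total charge of
−132 e. Surface receptors are three-bead tethers (frozen base, harmonic
linker, +1 e head) and counterions restore exact neutrality. This package
deliberately does **not** reproduce any specific mapped chemistry: the
template is generic and the nonbonded table
(`fcg_pair_table(eps_tail, eps_head_receptor, eps_guest_cross)`) exposes
the three couplings that control the physics — tail cohesion (how robust
the micelle is), head–receptor attraction (how hard the surface pulls on
it) and the guest–oligomer cross coupling (how tightly cargo is caged).
Guest–guest interactions keep the stated weak guest parameterization
(sigma = 0.43 nm, eps = 6.5 kJ/mol); the cross coupling defaults to
4.5 kJ/mol, strong enough that intact assemblies retain cargo on
simulation time scales yet weaker than the tail cohesion, so release is
promptly visible once the assembly opens. The defaults were calibrated
with short pilot runs to place the trivalent NP near the
adhesion/disassembly crossover, which is the regime of interest:
multivalent NPs that can both roll and exfoliate. Screened electrostatics
(eps_r = 15, the usual implicit-solvent dry-CG convention) supply a large
share of the head–receptor attraction, which is what makes adhesion scale
with valence: every oligomer carries three head beads regardless of
valence, and only the number of charged ones changes, so mono-, di- and
trivalent NPs share one scaffold and differ purely in charge.

Bead masses are 72 amu everywhere (4-heavy-atom CG convention); nothing in
this resolution pins the masses, and kinetics here are internally
consistent rather than absolutely calibrated (see Limitations).

## Force field terms

* LJ 12-6 and Coulomb/eps_r with a 1.1 nm cutoff. The dynamics engine uses
  cut-and-shifted potentials (energy continuous at the cutoff) for stable
  20 fs Langevin integration; the exported pair functions default to plain
  truncation, which is the textbook form their closed-form examples assume.
* A 9-3 wall `U = eps_w (3/sqrt(10)) ((2/15)(sigma_w/dz)^9 − (sigma_w/dz)^3)`
  mimics weak nonspecific NP–surface attraction and prevents penetration;
  the prefactor normalizes the well depth to exactly `eps_w` (default
  2.0 kJ/mol) at `dz = sigma_w (2/5)^{1/6}`. The 9-3 prefactor convention
  varies between MD engines; the physically quoted quantity is the well
  depth, so that is what the normalization fixes. `sigma_w` defaults to
  0.47 nm.
* Harmonic bonds and angles; nonbonded interactions between 1-2 and 1-3
  neighbors are excluded. Because branch tips (two heads on one core) are
  1-3 pairs, the oligomer template carries explicit spreading angles
  (109.5 degrees) so branches cannot collapse.
* A one-sided COM z-restraint `U = kappa (z_com − z0)^p` for `z_com > z0`
  (defaults z0 = 5 nm, kappa = 150, p = 2) keeps a pulled NP near the
  surface, and a constant force on the NP COM (default −100 kJ/mol/nm along
  x in the rolling preset) emulates flow-driven transport. COM forces are
  distributed mass-weighted so every group bead feels the same acceleration.

# Dynamics

The integrator is leapfrog stochastic (Langevin) dynamics:
`v ← exp(−gamma dt) v + (F/m) dt + sqrt((1 − exp(−2 gamma dt)) kB T/m) xi`,
`x ← x + v dt`, with 20 fs steps at 300 K in NVT. With gamma → 0 and noise
off it reduces to plain leapfrog (used by the energy-conservation test);
for a free particle the stationary kinetic temperature is exact. Frozen
beads (receptor anchors, mCG receptors) are excluded from integration —
forces on them are reported but never applied. Periodicity is x/y only,
matching the surface-slab geometry; reflecting boundaries close the
non-periodic z direction. Energies are logged with velocities synchronized
to the full step by a half kick, the standard leapfrog reporting
convention, so the logged total energy does not carry the O(omega dt)
half-step oscillation.

The per-bead friction gamma defaults to 1 ps^-1, a typical
implicit-solvent CG choice; all kinetic properties (drift mobility,
diffusion, first-passage times) are stated against this gamma. Absolute
time scales in implicit solvent are faster than experiment; comparisons in
this package are therefore internal (biased vs unbiased, dense vs sparse),
never absolute.

A step displacing any bead by more than half the cutoff marks the run
unstable; the last good frame is persisted and the trajectory flagged.

# Enhanced sampling

## Collective variables

* `com_xy` (and the 1D `com_x`): the NP COM position in the surface plane.
  Positions are integrated unwrapped, so the CV is continuous across the
  periodic boundaries; the bias grid itself is periodic over the box.
* `contacts`: the differentiable contact count
  `sum 1/(1 + (r/r0)^6)` over charged-bead/receptor-head pairs
  (value 1/2 exactly at r = r0; default r0 = 0.6 nm). The kernel widths of
  the deposition schedules carry no units in their original statement; they
  are interpreted here as nm for COM CVs and contact units for the contacts
  CV. A hard-cutoff contact count is kept separately in the observables for
  reporting.

## Metadynamics

Gaussian kernels of height `h` and per-dimension width are deposited every
`stride` steps; with a bias factor gamma_b the effective height is damped
well-tempered style, `h_eff = h exp(−V(s)/(kB T (gamma_b − 1)))`. COM-CV
biases are grid-backed (deposition adds the kernel to value and gradient
grids; evaluation is O(1) interpolation), which is what makes multi-million
step biased runs cheap; the contacts CV uses direct kernel summation, which
is exact and cheap at infrequent-deposition strides. Multiple walkers share
one bias, synchronizing at every deposition stride with a fixed merge
order, so the shared bias is deterministic given the per-walker seeds.
Whether the in-plane exploration schedule (h = 20 kJ/mol, width 1.0,
stride 5000) is well-tempered is not pinned by its source; standard
metadynamics is used there, with the bias factor reserved for the
infrequent-kinetics schedule where it is explicit.

For a converged well-tempered 1D bias, `F(s) = −V(s)/(1 − 1/gamma_b)` up to
a constant (`metad_free_energy()`); the test suite verifies recovery of an
analytic double well to within 0.5 kB T.

## Infrequent metadynamics and Poissonian kinetics

Rare unbinding kinetics use sparse well-tempered deposition on a CV that is
slow compared to the deposition stride, a stop condition (for unbinding:
switched contacts below 0.5 for 10 consecutive checks, so thermal noise
cannot trigger termination), and the acceleration factor
`alpha = <exp(beta V(s(t), t))>` time-averaged over the run (accumulated by
streaming log-sum-exp, so large biases cannot overflow). The unbiased
transition time is `t = alpha t_MetaD`. Repeating over seeds yields times
that, if the bias perturbs the transition state negligibly, are
exponentially distributed: `fit_poisson_tau()` estimates the characteristic
time tau by maximum likelihood (the sample mean) and checks
self-consistency with a two-sided KS test against Exp(tau),
`P(n>=1)(t) = 1 − exp(−t/tau)`. Censored runs (step budget exhausted) are
excluded from the MLE and reported separately. The estimator is validated
against brute-force mean first-passage times on a ~4 kB T double well,
where both routes are affordable.

# Observables

* `engagement_count()`: NP charged beads with at least one receptor head
  within the cutoff — bounded by the charged-bead count (132 for the
  44-oligomer trivalent NP), which is why it is the saturation-style
  adhesion metric; `pair_contact_count()` is the unbounded raw pair count.
* `sasa()`: Shrake–Rupley with Fibonacci sphere points; radii default to
  sigma/2 + 0.1 nm per type, probe 0.19 nm, 240 points (the isolated-sphere
  analytic value is recovered to ~1% at 960 points). `delta_sasa_percent()`
  reports 100 (SASA − SASA_ref)/SASA_ref; the reference is frame 0 of the
  analyzed run, the natural choice when production starts from the intact
  assembly.
* `guest_release()`: a guest is released at its first window of
  `persistence` consecutive frames (default 10) with zero contacts to the
  NP group; cumulative release % is non-decreasing by construction.
* `msd_and_velocity()`: time-lag-averaged COM MSD (unwrapped) and a linear
  drift-velocity fit.
* `region_occupancy()`: per-region fraction of frames by COM position.

# What the builders emulate — and what they do not

The builders produce *plausible initial states*, not equilibrium ensembles:
the one-bead NP is a jittered FCC sphere at the LJ-minimum spacing with
guests at the innermost sites, and the micelle builder places cores on a
Fibonacci sphere with tails inward/heads outward followed by a short
deterministic steepest-descent relaxation. This replaces the expensive
self-assembly MD a full study would run, with identical downstream physics
and desk-scale cost. Receptor placement is Poisson-disc by default (minimum
separation `1/sqrt(2 rho)`, enforced across region boundaries too); lattice
placement exists for exact-geometry tests. Realized receptor counts are
`round(area x rho)` half-away-from-zero, making density ratios exact
whenever the products are integral. Builders are bit-reproducible under a
fixed seed, and assembly with `neutralize = TRUE` yields a total charge of
exactly 0 e.

Passing tests on these synthetic systems demonstrate the machinery —
multivalent trapping, gradient-directed motion, force-driven exfoliation,
Poissonian unbinding — under controlled conditions. They do not calibrate
any real chemistry: mapping to a specific oligomer would require matching
dimerization free energies and assembly structure against finer-grained
reference simulations, which is out of scope here.

# Numerical choices and problem sizes

* Cutoff 1.1 nm, Verlet neighbor list with 0.4 nm skin, rebuilt on
  half-skin displacement; frozen–frozen pairs are skipped (they contribute
  a constant). Brute-force evaluation is available and exactly matches the
  listed path on small systems (a test asserts identity).
* Forces are validated against centered finite differences (max relative
  error < 1e-5) on random 50-bead systems constructed to keep all pairs
  away from the truncation radius, where the derivative of a truncated
  potential is undefined.
* The acceptance-scale experiments use deliberately small study systems: a
  200-monomer NP on a 12 x 6 nm two-region (64:1) surface for biased
  chemotaxis (2e5 steps x 10 seeds), and 16-oligomer mono- vs trivalent
  micelles with 6 guests pulled across a 6 x 6 nm-striped density
  gradient (0/0.12/0.52/1.12 nm^-2), 2e5 steps x 3 seeds per valence. These sizes are the package's chosen
  desk-scale study conditions; the packaged `*_full.yaml` presets state
  the full-size counterparts.
* Well-tempered recovery uses a 1.5e6-step run on the 1D toy; the
  kinetics validation uses 30 infrequent runs against 40 brute-force
  first-passage runs.
* Ties and degenerate inputs: a single-bead NP sits exactly at the origin;
  zero-density surfaces are valid and empty; stop conditions already true
  at t = 0 give a zero-time uncensored record with alpha = 1; all-censored
  input to the Poisson fit is an error, a single time gives the point MLE.

# Known limitations

* No explicit solvent, no PME/reaction-field electrostatics (plain shifted
  cutoff at 1.1 nm), no pressure coupling, no constraint algorithms.
* Absolute kinetics depend on the uncalibrated friction; only relative
  comparisons are meaningful.
* The contacts-CV bias force is O(|A| x |B|) per step — fine for the
  charged-bead/receptor groups it is meant for, not for biasing thousands
  of pairs.
* The micelle model is generic; its two exposed couplings are a
  caricature (a deliberately minimal one) of a chemically mapped force
  field.
* KS p-values for the Poisson self-consistency check use the fitted rate,
  which makes the test slightly conservative; with 30 samples this is
  immaterial for the factor-level agreement being checked.
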