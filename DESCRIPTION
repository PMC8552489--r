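Package: cgnp
Title: Coarse-Grained Simulation of Multivalent Nanoparticle Adhesion and
    Release Kinetics on Receptor-Functionalized Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builders, force fields, stochastic dynamics and enhanced-sampling
    tools for coarse-grained models of supramolecular nanoparticles that bind,
    roll along receptor-density gradients, disassemble and release encapsulated
    guests on functionalized surfaces. Provides seeded system builders
    (nanoparticles, tethered-receptor surfaces, counterions), a neighbor-listed
    Lennard-Jones/screened-Coulomb force field with a 9-3 surface wall, a
    leapfrog Langevin integrator with frozen beads and center-of-mass pulling,
    standard/well-tempered/multiple-walker/infrequent metadynamics on
    center-of-mass and contacts collective variables, the acceleration-factor
    estimator of unbiased transition times with Poissonian characteristic-time
    fitting, and trajectory observables (contacts, Shrake-Rupley SASA, guest
    release, MSD, region occupancy).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
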