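# Leapfrog Langevin integrator: determinism, limits, thermostat, pulling.

test_that("zero steps returns a single-frame trajectory equal to the input", {
  sys <- random_mixed_system(10, seed = 1)
  tr <- run_md(sys, 0, integrator_params(seed = 1), mcg_pair_table())
  expect_equal(length(tr$times), 1)
  expect_identical(tr$frames[[1]], sys$pos)
})

test_that("same seed and config give bit-identical trajectories", {
  sys <- random_mixed_system(20, seed = 2)
  pt <- mcg_pair_table()
  a <- run_md(sys, 500, integrator_params(seed = 11), pt, wall = wall_params())
  b <- run_md(sys, 500, integrator_params(seed = 11), pt, wall = wall_params())
  expect_identical(a$final_system$pos, b$final_system$pos)
  expect_identical(a$final_system$vel, b$final_system$vel)
  c <- run_md(sys, 500, integrator_params(seed = 12), pt, wall = wall_params())
  expect_false(identical(a$final_system$pos, c$final_system$pos))
})

test_that("with friction off and noise off the integrator conserves energy", {
  # harmonic dimer, symplectic leapfrog limit: windowed energy drift stays
  # tiny over 1e4 steps
  dimer <- cg_system(rbind(c(0, 0, 1), c(0.6, 0, 1)), c("M", "M"),
                     box = c(10, 10, 10),
                     bonds = matrix(c(1, 2, 0.5, 1000), 1))
  tr <- run_md(dimer, 1e4,
               integrator_params(gamma = 1e-12, noise = FALSE, seed = 1),
               free_pair_table(), log_stride = 1)
  etot <- tr$energies$bonded + tr$energies$kinetic
  w <- floor(length(etot) * 0.1)
  drift <- abs(mean(tail(etot, w)) - mean(head(etot, w))) / mean(abs(etot))
  expect_lt(drift, 1e-4)
})

test_that("the thermostat reaches the target temperature", {
  set.seed(3)
  gas <- cg_system(matrix(runif(300, 0, 15), 100, 3), rep("M", 100),
                   box = c(15, 15, 15))
  tr <- run_md(gas, 2e4, integrator_params(seed = 4), free_pair_table(),
               log_stride = 50)
  expect_equal(kinetic_temperature(tr), 300, tolerance = 0.02)
})

test_that("frozen beads stay bit-identical across all frames", {
  sp <- two_region_spec(8, 8, 0.5, 1, receptor_model = "monobead_frozen")
  surf <- build_surface(sp, seed = 1)
  np <- build_nanoparticle_mcg(20, seed = 1)
  sys <- assemble_system(np, surf)
  tr <- run_md(sys, 500, integrator_params(seed = 1), mcg_pair_table(),
               wall = wall_params(), frame_stride = 100)
  fro <- which(sys$frozen)
  for (f in tr$frames) expect_identical(f[fro, ], sys$pos[fro, ])
})

test_that("drift velocity under a constant COM force matches the Langevin mobility", {
  # stationary leapfrog drift: v = (F/m) dt / (1 - exp(-gamma dt))
  f_tot <- 100
  n <- 100
  expected <- (f_tot / n / 72) * 0.02 / (1 - exp(-0.02))
  vs <- vapply(1:5, function(s) {
    set.seed(s)
    gas <- cg_system(matrix(runif(3 * n, 0, 20), n, 3), rep("M", n),
                     box = c(20, 20, 20))
    gas$groups <- list(np_beads = seq_len(n))
    tr <- run_md(gas, 3e4, integrator_params(seed = 100 + s),
                 free_pair_table(),
                 external = external_force("np_beads", c(f_tot, 0, 0)),
                 frame_stride = 200)
    msd_and_velocity(tr, "np_beads", drift_axis = 1)$drift_velocity
  }, numeric(1))
  expect_equal(mean(vs), expected, tolerance = 0.1)
})

test_that("the COM z-restraint keeps a lifted NP near its onset", {
  np <- build_nanoparticle_mcg(30, seed = 2)
  surf <- build_surface(two_region_spec(10, 10, 0, 1), seed = 1, lz = 20)
  sys <- assemble_system(np, surf, z_offset = 4.5, lz = 20)
  tr <- run_md(sys, 2e4, integrator_params(seed = 5), mcg_pair_table(),
               wall = wall_params(),
               restraint = restraint_params(z0 = 5, kappa = 150, exp = 2),
               external = external_force("np_beads", c(0, 0, 200)),
               frame_stride = 500)
  ct <- com_trace(tr, "np_beads")
  z_late <- tail(ct$z, 10)
  expect_true(all(z_late > 4 & z_late < 7))  # pinned near the z0 = 5 onset
})

test_that("a blown-up step is flagged unstable and the last frame kept", {
  # two beads overlapping catastrophically
  sys <- cg_system(rbind(c(2, 2, 2), c(2.01, 2, 2)), c("M", "M"),
                   box = c(8, 8, 8))
  expect_warning(tr <- run_md(sys, 100, integrator_params(seed = 1),
                              mcg_pair_table()), "instab")
  expect_true(tr$unstable)
  expect_true(all(is.finite(tr$frames[[length(tr$frames)]])))
})
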