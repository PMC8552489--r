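# Pair potentials, wall, energy breakdown and force consistency.

test_that("LJ pair energy has the right zero and minima", {
  expect_equal(lj_pair_energy(0.47, 0.47, 10), 0)
  expect_equal(lj_pair_energy(2^(1 / 6) * 0.47, 0.47, 10), -10)
  expect_equal(lj_pair_energy(2^(1 / 6) * 0.35, 0.35, 40), -40)
  expect_equal(lj_pair_energy(2.0, 0.47, 10, rc = 1.1), 0)  # beyond cutoff
  expect_error(lj_pair_energy(0, 0.47, 10), "overlap")
})

test_that("screened Coulomb matches f q1 q2 / (eps_r r) and truncates", {
  expect_equal(coulomb_pair_energy(1.0, 1, -1, eps_r = 15),
               -138.935458 / 15, tolerance = 1e-12)
  expect_equal(coulomb_pair_energy(0.7, 0, 1), 0)
  expect_equal(coulomb_pair_energy(1.2, 1, -1, eps_r = 15, rc = 1.1), 0)
})

test_that("9-3 wall well depth equals eps at the analytic minimum", {
  wp <- wall_params(eps = 2.0, sigma = 0.47)
  zmin <- 0.47 * (2 / 5)^(1 / 6)
  expect_equal(wall_energy_93(zmin, wp), -2.0, tolerance = 1e-12)
  expect_lt(abs(wall_energy_93(100, wp)), 1e-6)       # asymptote
  expect_gt(wall_energy_93(0.1, wp), 0)               # repulsive core
  expect_error(wall_energy_93(-0.1, wp), "penetration")
  # numeric gradient sanity at random heights
  set.seed(1)
  z <- runif(20, 0.3, 3)
  h <- 1e-6
  fd <- -(wall_energy_93(z + h, wp) - wall_energy_93(z - h, wp)) / (2 * h)
  # compare against the analytic derivative used by the engine
  x3 <- (0.47 / z)^3
  dudz <- 2.0 * (3 / sqrt(10)) * (-(6 / 5) * x3^3 + 3 * x3) / z
  expect_equal(fd, -dudz, tolerance = 1e-6)
})

test_that("pair tables are symmetric and the minimalistic defaults are tabulated", {
  pt <- mcg_pair_table()
  expect_identical(pt$eps, t(pt$eps))
  expect_identical(pt$sigma, t(pt$sigma))
  expect_equal(pt$eps["M", "M"], 10)
  expect_equal(pt$eps["M", "R"], 40)
  expect_equal(pt$sigma["M", "R"], 0.35)
  expect_equal(pt$sigma["G", "G"], 0.43)
  expect_equal(pt$eps["G", "M"], 6.5)
  ft <- fcg_pair_table()
  expect_identical(ft$eps, t(ft$eps))
})

test_that("two beads at the LJ minimum have energy -eps and vanishing force", {
  sys <- cg_system(rbind(c(2, 2, 2), c(2 + 2^(1 / 6) * 0.47, 2, 2)),
                   c("M", "M"), box = c(10, 10, 10))
  pt <- mcg_pair_table()
  pt$lj_shift <- FALSE
  ef <- total_energy_forces(sys, pt)
  expect_equal(ef$energy$total, -10, tolerance = 1e-12)
  expect_lt(max(abs(ef$forces)), 1e-8)
})

test_that("energy is invariant under full-box x/y translations", {
  sys <- random_mixed_system(40, seed = 7)
  pt <- mcg_pair_table()
  e0 <- total_energy_forces(sys, pt, wall = wall_params())$energy
  shifted <- sys
  shifted$pos[, 1] <- shifted$pos[, 1] + sys$box[1]
  shifted$pos[, 2] <- shifted$pos[, 2] - 2 * sys$box[2]
  e1 <- total_energy_forces(shifted, pt, wall = wall_params())$energy
  expect_equal(e1$total, e0$total, tolerance = 1e-10)
  expect_equal(e1$lj, e0$lj, tolerance = 1e-10)
  expect_equal(e1$coulomb, e0$coulomb, tolerance = 1e-10)
})

test_that("neighbor-listed evaluation equals brute force exactly", {
  for (seed in c(1, 2, 3)) {
    sys <- random_mixed_system(60, seed = seed)
    pt <- mcg_pair_table()
    a <- total_energy_forces(sys, pt, wall = wall_params())
    b <- total_energy_forces(sys, pt, wall = wall_params(),
                             use_neighbor_list = FALSE)
    expect_identical(a$energy$total, b$energy$total)
    expect_identical(a$forces, b$forces)
  }
})

test_that("analytic forces match centered finite differences (all terms)", {
  np <- build_nanoparticle_fcg(oligomer_template(), 4, 2, seed = 1,
                               relax = FALSE)
  np$box <- c(12, 12, 12)
  np$periodic <- c(TRUE, TRUE, FALSE)
  np$pos <- sweep(np$pos, 2, c(6, 6, 4), "+")
  np$groups$all <- seq_len(n_beads(np))
  pt <- fcg_pair_table()
  args <- list(wall = wall_params(),
               restraint = restraint_params(z0 = 3, group = "all"))
  f <- do.call(total_energy_forces, c(list(np, pt), args))$forces
  fd <- do.call(fd_forces, c(list(np, pt), args))
  expect_lt(max(abs(f - fd)) / max(abs(f)), 1e-5)
})

test_that("energy breakdown components sum to the total", {
  sys <- random_mixed_system(30, seed = 9)
  pt <- mcg_pair_table()
  en <- total_energy_forces(sys, pt, wall = wall_params())$energy
  expect_equal(en$total,
               en$lj + en$coulomb + en$wall + en$bonded + en$restraint +
                 en$external)
})

test_that("forces on frozen beads are reported but beads never move", {
  sys <- cg_system(rbind(c(1, 1, 0), c(1, 1, 0.45)), c("R", "M"),
                   box = c(5, 5, 5))
  ef <- total_energy_forces(sys, mcg_pair_table())
  expect_gt(abs(ef$forces[1, 3]), 0)  # force reported on the frozen bead
  tr <- run_md(sys, 200, integrator_params(seed = 1), mcg_pair_table(),
               wall = wall_params())
  expect_identical(tr$final_system$pos[1, ], c(1, 1, 0))
})
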