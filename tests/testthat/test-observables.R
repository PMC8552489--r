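# Analysis statistics: engagement, SASA, release, MSD, occupancy.

make_static_traj <- function(frames, sys, dt = 1) {
  structure(list(times = (seq_along(frames) - 1) * dt, frames = frames,
                 energies = NULL, final_system = {
                   sys$pos <- frames[[length(frames)]]
                   sys
                 }, stopped = FALSE, unstable = FALSE, stop_step = -1,
                 metadata = list()), class = "cg_trajectory")
}

test_that("engagement counts beads with a receptor within the cutoff, bounded by the group size", {
  # 3 charged beads, 5 receptor heads: one bead touching two receptors
  # still counts once
  pos <- rbind(c(0, 0, 0.5), c(2, 0, 0.5), c(4, 0, 5),
               c(0, 0, 0), c(0.1, 0, 0), c(2, 0, 0), c(6, 0, 0), c(8, 0, 0))
  sys <- cg_system(pos, c("H", "H", "H", "RH", "RH", "RH", "RH", "RH"),
                   box = c(20, 20, 20))
  sys$groups <- list(np_charged_beads = 1:3, receptor_heads = 4:8)
  expect_equal(engagement_count(sys, cutoff = 0.6), 2)
  expect_gte(pair_contact_count(sys, cutoff = 0.6), 3)
  sys$pos[, 3] <- sys$pos[, 3] + 50  # move NP far away
  sys$pos[4:8, 3] <- sys$pos[4:8, 3] - 50
  expect_equal(engagement_count(sys, cutoff = 0.6), 0)
})

test_that("engagement saturates at the NP charged-bead count", {
  np <- build_nanoparticle_fcg(oligomer_template(), 44, 0, seed = 1,
                               relax = FALSE)
  nq <- length(np$groups$np_charged_beads)
  # put one receptor head right on top of every charged bead
  heads <- np$pos[np$groups$np_charged_beads, , drop = FALSE]
  heads[, 3] <- heads[, 3] + 0.3
  sys <- merge_systems(np, {
    s <- cg_system(heads, rep("RH", nq), box = np$box)
    s$groups <- list(receptor_heads = seq_len(nq))
    s
  })
  expect_equal(engagement_count(sys), nq)
  expect_equal(nq, 132)
})

test_that("SASA: isolated sphere analytic, additivity, and burial", {
  one <- cg_system(matrix(c(1, 1, 1), 1, 3), "M", box = c(50, 50, 50))
  one$groups <- list(g = 1L)
  r <- one$types$radius[one$type[1]]
  a1 <- sasa(one, "g", probe = 0.19, n_sphere_points = 960)
  expect_equal(a1, 4 * pi * (r + 0.19)^2, tolerance = 0.01)
  # two well-separated beads: sum of singles
  two <- cg_system(rbind(c(1, 1, 1), c(10, 10, 10)), c("M", "M"),
                   box = c(50, 50, 50))
  two$groups <- list(g = 1:2)
  expect_equal(sasa(two, "g", n_sphere_points = 960), 2 * a1,
               tolerance = 1e-6)
  # a bead buried under a tight shell contributes nothing
  shell <- rbind(c(0, 0, 0), 0.5 * fibonacci_dirs(40))
  bur <- cg_system(shell, rep("M", 41), box = c(50, 50, 50))
  bur$groups <- list(center = 1L, all = 1:41)
  per_bead <- sasa_cpp(bur$pos, rep(bur$types$radius[1], 41), 0.19, 480)
  expect_lt(per_bead[1], 0.01)
})

test_that("delta-SASA percentages are relative to the reference frame", {
  ss <- data.frame(time = 0:2, sasa = c(50, 50, 100))
  ds <- delta_sasa_percent(ss)
  expect_equal(ds$delta_sasa_pct, c(0, 0, 100))
  expect_error(delta_sasa_percent(data.frame(time = 0, sasa = 0)), "reference")
})

test_that("guest release is cumulative, bounded and matches constructed cases", {
  # 2 guests, 1 monomer; guest 1 leaves at frame 4, guest 2 never leaves
  nfr <- 20
  frames <- lapply(seq_len(nfr), function(f) {
    g1 <- if (f >= 4) c(10, 0, 0) else c(0.4, 0, 0)
    rbind(g1, c(-0.4, 0, 0), c(0, 0, 0))
  })
  sys <- cg_system(frames[[1]], c("G", "G", "M"), box = c(30, 30, 30))
  sys$groups <- list(guest_beads = 1:2, np_beads = 1:3)
  tr <- make_static_traj(frames, sys)
  rep5 <- guest_release(tr, persistence = 5)
  expect_equal(rep5$final_pct, 50)
  expect_true(all(diff(rep5$series$release_pct) >= 0))
  expect_true(is.na(rep5$release_time[2]))
  # all guests isolated from frame 0 -> 100% at the first persistent window
  frames2 <- replicate(nfr, rbind(c(10, 0, 0), c(-10, 0, 0), c(0, 0, 0)),
                       simplify = FALSE)
  tr2 <- make_static_traj(frames2, sys)
  rep2 <- guest_release(tr2, persistence = 5)
  expect_equal(rep2$final_pct, 100)
  expect_equal(rep2$series$release_pct[5], 100)
  expect_equal(rep2$series$release_pct[4], 0)
  # intact NP throughout -> 0%
  frames3 <- replicate(nfr, rbind(c(0.4, 0, 0), c(-0.4, 0, 0), c(0, 0, 0)),
                       simplify = FALSE)
  expect_equal(guest_release(make_static_traj(frames3, sys))$final_pct, 0)
})

test_that("MSD of a static group is zero; a drifting group has the set velocity", {
  sys <- cg_system(matrix(1, 3, 3), rep("M", 3), box = c(50, 50, 50))
  sys$groups <- list(g = 1:3)
  still <- make_static_traj(replicate(10, matrix(1, 3, 3), simplify = FALSE), sys)
  mv <- msd_and_velocity(still, "g")
  expect_true(all(mv$msd$msd == 0))
  expect_equal(mv$drift_velocity, 0)
  drift <- make_static_traj(lapply(0:9, function(f) matrix(1, 3, 3) +
                                     cbind(rep(0.25 * f, 3), 0, 0)), sys)
  mv2 <- msd_and_velocity(drift, "g", drift_axis = 1)
  expect_equal(mv2$drift_velocity, 0.25, tolerance = 1e-10)
  expect_error(msd_and_velocity(make_static_traj(list(matrix(1, 3, 3)), sys), "g"),
               "2 frames")
})

test_that("free 2D Brownian motion satisfies the Einstein relation", {
  # leapfrog Langevin free particle: D = kB T / (m gamma) per axis
  d_expect <- kB() * 300 / (72 * 1.0)
  msds <- vapply(1:20, function(s) {
    gas <- cg_system(matrix(5, 1, 3), "M", box = c(1e4, 1e4, 1e4),
                     periodic = c(FALSE, FALSE, FALSE))
    gas$groups <- list(g = 1L)
    tr <- run_md(gas, 4e4, integrator_params(seed = 400 + s),
                 free_pair_table(), frame_stride = 100)
    mv <- msd_and_velocity(tr, "g", axes = c(1, 2), max_lag_frac = 0.25)
    # slope of MSD(lag) = 4 D lag
    unname(coef(lm(mv$msd$msd ~ mv$msd$lag))[2]) / 4
  }, numeric(1))
  expect_equal(mean(msds), d_expect, tolerance = 0.1)
})

test_that("region occupancy fractions sum to one and follow the COM", {
  spec <- two_region_spec(10, 10, 1, 0.5)
  sys <- cg_system(matrix(c(2, 5, 1), 1, 3), "M", box = c(10, 10, 10))
  sys$groups <- list(np_beads = 1L)
  pinned <- make_static_traj(replicate(8, matrix(c(2, 5, 1), 1, 3),
                                       simplify = FALSE), sys)
  occ <- region_occupancy(pinned, spec)
  expect_equal(sum(occ$fraction), 1)
  expect_equal(occ$fraction, c(1, 0))
  # a uniform sweep across x splits in proportion to region areas
  sweep_tr <- make_static_traj(lapply(seq(0.05, 9.95, length.out = 100),
                                      function(x) matrix(c(x, 5, 1), 1, 3)), sys)
  occ2 <- region_occupancy(sweep_tr, spec)
  expect_equal(occ2$fraction, c(0.5, 0.5), tolerance = 0.03)
})
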