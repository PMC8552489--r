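# System builders: nanoparticles, surfaces, assembly, counterions.

test_that("single-bead NP builder places monomers and interior guests deterministically", {
  np <- build_nanoparticle_mcg(100, 5, seed = 3)
  np2 <- build_nanoparticle_mcg(100, 5, seed = 3)
  expect_identical(np$pos, np2$pos)  # bit-reproducible under a fixed seed
  expect_equal(n_beads(np), 105)
  expect_gte(min(stats::dist(np$pos)), 0.9 * 0.43)
  # guests sit inside the monomer shell: every guest closer to the COM than
  # the outermost monomer
  rg <- sqrt(rowSums(np$pos[np$groups$guest_beads, , drop = FALSE]^2))
  rm_ <- sqrt(rowSums(np$pos[np$groups$monomer_beads, , drop = FALSE]^2))
  expect_lt(max(rg), max(rm_))

  # degenerate single-bead cluster at the origin
  one <- build_nanoparticle_mcg(1, 0, seed = 7)
  expect_equal(one$pos, matrix(0, 1, 3))

  # full-size build matches the reference composition
  big <- build_nanoparticle_mcg(1925, 12, seed = 1)
  expect_equal(n_beads(big), 1937)
  expect_gte(min(stats::dist(big$pos)), 0.9 * 0.43)
})

test_that("too small a packing radius is an infeasible-density error", {
  expect_error(build_nanoparticle_mcg(500, 0, packing_radius = 1.0),
               "infeasible")
})

test_that("oligomer template is a tree sharing one scaffold across valences", {
  tpl <- oligomer_template(n_tails = 3, tail_length = 2, n_charged_heads = 2)
  expect_equal(tpl$n_beads, 1 + 6 + 3)  # core + tails + all heads
  expect_equal(nrow(tpl$bonds), tpl$n_beads - 1)  # acyclic + connected
  expect_equal(sum(tpl$type == "H"), 2)   # charged heads
  expect_equal(sum(tpl$type == "HN"), 1)  # neutral head
  # valences differ only in charge, never in bead count
  expect_equal(oligomer_template(n_charged_heads = 1)$n_beads,
               oligomer_template(n_charged_heads = 3)$n_beads)
})

test_that("micelle builder yields the stated total charge per valence", {
  for (nh in c(1, 3)) {
    np <- build_nanoparticle_fcg(oligomer_template(n_charged_heads = nh),
                                 44, 10, seed = 1, relax = FALSE)
    expect_equal(total_charge(np), -44 * nh)
    expect_equal(length(np$groups$np_charged_beads), 44 * nh)
    expect_equal(length(np$groups$guest_beads), 10)
  }
  single <- build_nanoparticle_fcg(oligomer_template(), 1, 0, seed = 2,
                                   relax = FALSE)
  expect_equal(total_charge(single), -3)
})

test_that("micelle geometry: tails inward, charged heads outward, guests interior", {
  np <- build_nanoparticle_fcg(oligomer_template(), 24, 6, seed = 1)
  com <- center_of_mass(np, seq_len(n_beads(np)))
  rad <- function(g) mean(sqrt(rowSums(sweep(np$pos[g, , drop = FALSE], 2, com)^2)))
  expect_lt(rad(np$groups$tail_beads), rad(np$groups$core_beads))
  expect_gt(rad(np$groups$np_charged_beads), rad(np$groups$tail_beads))
  expect_lt(rad(np$groups$guest_beads), rad(np$groups$core_beads))
})

test_that("surface builder realizes round(area x rho) receptors per region", {
  # uniform 20 x 20 at 1/nm^2, tethered three-bead receptors
  sp <- two_region_spec(20, 20, 1.0, 1.0, receptor_model = "tribead_tethered")
  surf <- build_surface(sp, seed = 1)
  expect_equal(sum(surf$meta$region_counts), 400)
  expect_equal(n_beads(surf), 1200)
  expect_equal(length(surf$groups$receptor_heads), 400)

  # empty spec
  empty <- build_surface(two_region_spec(10, 10, 0, 0.5), seed = 1)
  expect_equal(n_beads(empty), 0)

  # 64:1 two-region ratio is exact when area x rho is integral
  sp64 <- two_region_spec(32, 32, 1.0, 1 / 64)
  rd <- realized_densities(build_surface(sp64, seed = 2))
  expect_equal(rd$rho_realized[1] / rd$rho_realized[2], 1 / 64)
})

test_that("receptor-count rounding is half-away-from-zero on area x rho", {
  # 5 x 5 region at 0.09/nm^2: 2.25 -> 2; at 0.1: 2.5 -> 3 (not banker's 2)
  s1 <- surface_spec(5, 5, data.frame(x0 = 0, x1 = 5, y0 = 0, y1 = 5,
                                      rho = 0.09))
  expect_equal(build_surface(s1, 1)$meta$region_counts, 2L)
  s2 <- surface_spec(5, 5, data.frame(x0 = 0, x1 = 5, y0 = 0, y1 = 5,
                                      rho = 0.1))
  expect_equal(build_surface(s2, 1)$meta$region_counts, 3L)
})

test_that("gradient stripes realize the printed density ladder", {
  gs <- gradient_stripes_spec(c(0, 0.12, 0.52, 1.12), 30, 30)
  expect_equal(gs$lx, 120)
  surf <- build_surface(gs, seed = 2)
  expect_equal(surf$meta$region_counts, round(900 * c(0, 0.12, 0.52, 1.12)))
  rd <- realized_densities(surf)
  expect_equal(rd$rho_realized, c(0, 0.12, 0.52, 1.12))
  # single and empty stripes
  expect_equal(build_surface(gradient_stripes_spec(0.5, 10, 10),
                             seed = 1)$meta$region_counts, 50L)
  expect_equal(n_beads(build_surface(gradient_stripes_spec(c(0, 0), 5, 5),
                                     seed = 1)), 0)
})

test_that("poisson_disc placement respects the minimum separation", {
  sp <- surface_spec(10, 10, data.frame(x0 = 0, x1 = 10, y0 = 0, y1 = 10,
                                        rho = 0.5), placement = "poisson_disc")
  surf <- build_surface(sp, seed = 4)
  d <- stats::dist(surf$pos[, 1:2])
  expect_gte(min(d), 1 / sqrt(2 * 0.5) - 1e-12)
})

test_that("overlapping or non-tiling regions are rejected", {
  expect_error(surface_spec(10, 10, data.frame(
    x0 = c(0, 4), x1 = c(6, 10), y0 = 0, y1 = 10, rho = 1)), "overlap")
  expect_error(surface_spec(10, 10, data.frame(
    x0 = 0, x1 = 5, y0 = 0, y1 = 10, rho = 1)), "tile")
})

test_that("assembly neutralizes the charge with counterions and is seeded", {
  np <- build_nanoparticle_fcg(oligomer_template(), 8, 2, seed = 1)
  surf <- build_surface(two_region_spec(12, 12, 0.2, 1,
                                        receptor_model = "tribead_tethered"),
                        seed = 1)
  sys <- assemble_system(np, surf, neutralize = TRUE, seed = 5)
  expect_equal(total_charge(sys), 0)
  sys2 <- assemble_system(np, surf, neutralize = TRUE, seed = 5)
  expect_identical(sys$pos, sys2$pos)
  # uncharged NP on an uncharged surface needs no ions
  mnp <- build_nanoparticle_mcg(30, seed = 1)
  msurf <- build_surface(two_region_spec(10, 10, 0.3, 1), seed = 1)
  msys <- assemble_system(mnp, msurf, neutralize = TRUE)
  expect_null(msys$groups$counterions)
  expect_equal(total_charge(msys), 0)
})

test_that("assembly rejects an NP placed into the surface", {
  np <- build_nanoparticle_mcg(50, seed = 1)
  surf <- build_surface(two_region_spec(10, 10, 1, 1), seed = 1)
  expect_error(assemble_system(np, surf, z_offset = 0), "overlap")
})

test_that("fresh assemblies have no overlapping beads", {
  np <- build_nanoparticle_fcg(oligomer_template(), 16, 6, seed = 2)
  surf <- build_surface(gradient_stripes_spec(c(0.12, 0.52), 8, 8), seed = 2)
  sys <- assemble_system(np, surf, seed = 2)
  d <- min_image_dist(sys$pos, sys$box)
  expect_gte(min(d), 0.9 * 0.35)
})
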