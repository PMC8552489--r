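# Nonbonded pair tables, analytic pair potentials, the 9-3 surface wall and
# parameter containers for the COM z-restraint.

#' Pair interaction table
#'
#' Per-type-pair Lennard-Jones 12-6 parameters plus global cutoff and
#' dielectric settings. Pairs not explicitly tabulated use Lorentz-Berthelot
#' mixing of the per-type `sigma0`/`eps0` values.
#'
#' @param types character vector of type names (must cover every type used
#'   by the systems this table is applied to).
#' @param sigma0,eps0 per-type self parameters used for Lorentz-Berthelot
#'   mixing (nm, kJ/mol); recycled.
#' @param rc global LJ/Coulomb cutoff, nm (default 1.1).
#' @param eps_r relative dielectric constant (default 15, implicit-solvent
#'   screening).
#' @param lj_shift,coul_shift logical; cut-and-shift the potentials so the
#'   energy is continuous at `rc` (default TRUE; used by the integrator).
#' @return object of class `pair_table` with `sigma`/`eps` matrices.
#' @export
pair_table <- function(types, sigma0 = 0.47, eps0 = 2.0, rc = 1.1,
                       eps_r = 15, lj_shift = TRUE, coul_shift = TRUE) {
  nt <- length(types)
  sigma0 <- rep_len(sigma0, nt)
  eps0 <- rep_len(eps0, nt)
  sigma <- outer(sigma0, sigma0, function(a, b) (a + b) / 2)
  eps <- outer(eps0, eps0, function(a, b) sqrt(a * b))
  dimnames(sigma) <- dimnames(eps) <- list(types, types)
  stopifnot(rc > max(sigma))
  structure(list(types = types, sigma = sigma, eps = eps, rc = rc,
                 eps_r = eps_r, lj_shift = lj_shift, coul_shift = coul_shift),
            class = "pair_table")
}

#' Set an explicit pair parameterization
#'
#' @param pt a `pair_table`.
#' @param t1,t2 type names.
#' @param sigma,eps LJ parameters (nm, kJ/mol).
#' @return the modified `pair_table`.
#' @export
set_pair <- function(pt, t1, t2, sigma, eps) {
  stopifnot(t1 %in% pt$types, t2 %in% pt$types, sigma >= 0, eps >= 0)
  pt$sigma[t1, t2] <- pt$sigma[t2, t1] <- sigma
  pt$eps[t1, t2] <- pt$eps[t2, t1] <- eps
  pt
}

#' @export
print.pair_table <- function(x, ...) {
  cat("<pair_table>", length(x$types), "types; rc =", x$rc,
      "nm; eps_r =", x$eps_r, "\n")
  print(round(x$eps, 2))
  invisible(x)
}

#' Minimalistic (single-bead-per-monomer) pair table
#'
#' The default one-bead model: monomer-monomer self-assembly well
#' (sigma 0.47 nm, eps 10 kJ/mol) and a four-fold deeper monomer-receptor
#' binding well (sigma 0.35 nm, eps 40 kJ/mol), so the assembly/binding
#' ratio is 1/4. Guest interactions use the guest parameterization
#' (sigma 0.43 nm, eps 6.5 kJ/mol). The well depths are exposed so the
#' assembly-vs-binding energy competition can be scanned.
#'
#' @param e_ass monomer-monomer well depth, kJ/mol (default 10).
#' @param e_bind monomer-receptor well depth, kJ/mol (default 40).
#' @return a `pair_table` over types M (monomer), G (guest), R (receptor).
#' @export
mcg_pair_table <- function(e_ass = 10, e_bind = 40) {
  pt <- pair_table(c("M", "G", "R"), sigma0 = c(0.47, 0.43, 0.47),
                   eps0 = c(e_ass, 6.5, 0))
  pt <- set_pair(pt, "M", "M", 0.47, e_ass)
  pt <- set_pair(pt, "M", "R", 0.35, e_bind)
  pt <- set_pair(pt, "M", "G", 0.43, 6.5)
  pt <- set_pair(pt, "G", "G", 0.43, 6.5)
  pt <- set_pair(pt, "G", "R", 0.43, 6.5)
  pt <- set_pair(pt, "R", "R", 0.47, 0)  # frozen-frozen, never evaluated
  pt
}

#' Generic oligomer (micelle) pair table
#'
#' A MARTINI-flavored generic parameterization for the finer model:
#' hydrophobic tails cohere, charged heads interact mainly through screened
#' electrostatics, guests use the stated weak guest parameters
#' (sigma 0.43 nm, eps 6.5 kJ/mol) so their release is promptly visible on
#' disassembly.
#'
#' @param eps_tail tail-tail cohesion well depth, kJ/mol (default 3.5).
#' @param eps_head_receptor LJ part of the charged-head/receptor-head
#'   contact, kJ/mol (default 6.0; screened electrostatics add the rest of
#'   the attraction).
#' @param eps_guest_cross guest/oligomer cross well depth, kJ/mol (default
#'   4.5): stronger than a thermal fluctuation, so intact assemblies retain
#'   their cargo on simulation time scales, but weaker than the tail
#'   cohesion, so guests do not glue the assembly together and leave
#'   promptly once it opens.
#' @return a `pair_table` over the oligomer/receptor/counterion types.
#' @export
fcg_pair_table <- function(eps_tail = 3.5, eps_head_receptor = 6.0,
                           eps_guest_cross = 4.5) {
  types <- c("C", "T", "H", "HN", "G", "RB", "RL", "RH", "ION", "IONM")
  pt <- pair_table(types,
                   sigma0 = c(0.47, 0.47, 0.47, 0.47, 0.43, 0.47, 0.47, 0.47, 0.47, 0.47),
                   eps0   = c(3.5, eps_tail, 2.0, 2.0, 6.5, 2.0, 2.0, 2.0, 1.0, 1.0))
  pt <- set_pair(pt, "C", "T", 0.47, (3.5 + eps_tail) / 2)
  pt <- set_pair(pt, "H", "RH", 0.47, eps_head_receptor)
  for (t in c("C", "T", "H", "HN")) pt <- set_pair(pt, t, "G", 0.45, eps_guest_cross)
  pt <- set_pair(pt, "G", "G", 0.43, 6.5)
  pt
}

#' Lennard-Jones 12-6 pair energy
#'
#' U(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6), truncated at `rc` and
#' optionally shifted so U(rc) = 0.
#'
#' @param r separation, nm (vectorized).
#' @param sigma,eps LJ parameters (nm, kJ/mol).
#' @param rc cutoff, nm (default `Inf`: no truncation).
#' @param shift logical; subtract U(rc) inside the cutoff.
#' @return energy, kJ/mol.
#' @export
lj_pair_energy <- function(r, sigma, eps, rc = Inf, shift = FALSE) {
  if (any(r <= 0)) stop("bead overlap: r must be > 0")
  sr6 <- (sigma / r)^6
  u <- 4 * eps * (sr6^2 - sr6)
  if (shift && is.finite(rc)) {
    src6 <- (sigma / rc)^6
    u <- u - 4 * eps * (src6^2 - src6)
  }
  u[r >= rc] <- 0
  u
}

#' Screened Coulomb pair energy
#'
#' U(r) = f qi qj / (eps_r r) with f = 138.935458 kJ mol^-1 nm e^-2,
#' truncated at `rc`.
#'
#' @param r separation, nm (vectorized).
#' @param qi,qj charges, e.
#' @param eps_r relative dielectric constant (default 15).
#' @param rc cutoff, nm (default `Inf`).
#' @param shift logical; subtract U(rc) inside the cutoff.
#' @return energy, kJ/mol.
#' @export
coulomb_pair_energy <- function(r, qi, qj, eps_r = 15, rc = Inf, shift = FALSE) {
  if (any(r <= 0)) stop("bead overlap: r must be > 0")
  pref <- .f_coulomb * qi * qj / eps_r
  u <- pref / r
  if (shift && is.finite(rc)) u <- u - pref / rc
  u[r >= rc] <- 0
  u
}

#' 9-3 surface wall parameters
#'
#' @param eps well depth, kJ/mol (default 2.0: weak nonspecific
#'   surface attraction).
#' @param sigma wall length scale, nm (default 0.47).
#' @param zref surface plane, nm (default 0).
#' @return a `wall_params` list.
#' @export
wall_params <- function(eps = 2.0, sigma = 0.47, zref = 0) {
  stopifnot(eps >= 0, sigma > 0)
  structure(list(eps = eps, sigma = sigma, zref = zref), class = "wall_params")
}

#' 9-3 surface wall energy
#'
#' U(dz) = eps (3/sqrt(10)) ((2/15)(sigma/dz)^9 - (sigma/dz)^3) with
#' dz = z - zref; the prefactor normalizes the well depth to exactly `eps`,
#' reached at dz = sigma (2/5)^(1/6).
#'
#' @param z height, nm (vectorized); must exceed `params$zref`.
#' @param params a [wall_params()] object.
#' @return energy, kJ/mol.
#' @export
wall_energy_93 <- function(z, params) {
  dz <- z - params$zref
  if (any(dz <= 0)) stop("surface penetration: z must exceed zref")
  x3 <- (params$sigma / dz)^3
  params$eps * (3 / sqrt(10)) * ((2 / 15) * x3^3 - x3)
}

#' One-sided COM z-restraint parameters
#'
#' U = kappa (z_com - z0)^exp applied only when the group's center of mass
#' exceeds z0 (an upper wall keeping the assembly near the surface).
#'
#' @param z0 onset height, nm (default 5).
#' @param kappa force constant, kJ mol^-1 nm^-exp (default 150).
#' @param exp integer exponent (default 2).
#' @param group bead-group name the restraint acts on (default
#'   `"np_beads"`).
#' @return a `restraint_params` list.
#' @export
restraint_params <- function(z0 = 5, kappa = 150, exp = 2, group = "np_beads") {
  stopifnot(kappa >= 0, exp >= 1)
  structure(list(z0 = z0, kappa = kappa, exp = as.integer(exp), group = group),
            class = "restraint_params")
}

#' Constant center-of-mass force
#'
#' A constant force applied to a group's center of mass (distributed over
#' the group mass-weighted, so every bead feels the same acceleration).
#'
#' @param group bead-group name.
#' @param vector length-3 force, kJ mol^-1 nm^-1.
#' @return an `external_force` list.
#' @export
external_force <- function(group, vector) {
  stopifnot(length(vector) == 3)
  structure(list(group = group, vector = as.numeric(vector)),
            class = "external_force")
}

# Assemble the flat force-field list handed to the C++ engine.
build_ff_list <- function(system, pt, wall = NULL, restraint = NULL,
                          external = NULL, double_well = NULL) {
  reg <- system$types$name
  used <- reg[sort(unique(system$type))]
  miss <- setdiff(used, pt$types)
  if (length(miss)) stop("pair table lacks types: ", paste(miss, collapse = ", "))
  nt <- length(reg)
  sigma <- matrix(0, nt, nt)
  eps <- matrix(0, nt, nt)
  present <- which(reg %in% pt$types)
  idx <- match(reg[present], pt$types)
  sigma[present, present] <- pt$sigma[idx, idx]
  eps[present, present] <- pt$eps[idx, idx]
  ff <- list(sigma = sigma, eps = eps,
             rc = pt$rc, eps_r = pt$eps_r,
             lj_shift = pt$lj_shift, coul_shift = pt$coul_shift)
  if (!is.null(wall)) {
    ff$wall <- list(eps = wall$eps, sigma = wall$sigma, zref = wall$zref)
  }
  if (!is.null(restraint)) {
    ff$restraint <- list(z0 = restraint$z0, kappa = restraint$kappa,
                         exp = restraint$exp,
                         group = get_group(system, restraint$group))
  }
  if (!is.null(external)) {
    ff$pull <- list(force = external$vector,
                    group = get_group(system, external$group))
  }
  if (!is.null(double_well)) {
    ff$double_well <- list(barrier = double_well$barrier,
                           half_sep = double_well$half_sep)
  }
  ff
}

#' Total potential energy and forces
#'
#' Evaluates all force-field terms for a system: neighbor-listed LJ and
#' screened Coulomb under minimum-image convention in x/y, harmonic bonds
#' and angles (1-2 and 1-3 pairs excluded from nonbonded sums), the 9-3
#' wall, the one-sided COM z-restraint and any external terms. Pairs where
#' both beads are frozen are skipped (they contribute a constant).
#'
#' @param system a `cg_system`.
#' @param pt a `pair_table`.
#' @param wall optional [wall_params()].
#' @param restraint optional [restraint_params()].
#' @param external optional [external_force()].
#' @param double_well optional 1D double-well `list(barrier, half_sep)`
#'   (toy systems).
#' @param use_neighbor_list logical; FALSE forces brute-force all-pairs
#'   evaluation (identical result, used for verification).
#' @return `list(energy = <breakdown list>, forces = <N x 3 matrix>)`;
#'   `energy$total` is the sum of the components. Forces on frozen beads
#'   are reported but never applied by the integrator.
#' @export
total_energy_forces <- function(system, pt, wall = NULL, restraint = NULL,
                                external = NULL, double_well = NULL,
                                use_neighbor_list = TRUE) {
  ff <- build_ff_list(system, pt, wall, restraint, external, double_well)
  energy_forces_cpp(unclass(system), ff, use_neighbor_list)
}
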