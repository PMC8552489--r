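# System container: bead coordinates/velocities/charges/types, topology
# (bonds, angles, named groups, frozen mask) and a box periodic in x and y.

#' Bead type table
#'
#' Defines a set of coarse-grained bead types. Masses default to 72 amu
#' (the usual 4-heavy-atom CG mapping); radii are used only by the SASA
#' observable.
#'
#' @param name character vector of type names.
#' @param mass numeric, amu.
#' @param charge numeric, elementary charges.
#' @param radius numeric, nm (SASA radius).
#' @param role character; one of `"monomer"`, `"guest"`, `"oligomer-core"`,
#'   `"oligomer-tail"`, `"oligomer-head-charged"`, `"receptor-base"`,
#'   `"receptor-linker"`, `"receptor-head"`, `"counterion"`.
#' @param frozen logical; frozen beads are excluded from integration.
#' @return a `data.frame` with one row per type.
#' @export
bead_types <- function(name, mass = 72, charge = 0, radius = 0.335,
                       role = "monomer", frozen = FALSE) {
  df <- data.frame(name = as.character(name), mass = mass, charge = charge,
                   radius = radius, role = role, frozen = frozen,
                   stringsAsFactors = FALSE)
  valid_roles <- c("monomer", "guest", "oligomer-core", "oligomer-tail",
                   "oligomer-head-charged", "oligomer-head-neutral",
                   "receptor-base", "receptor-linker",
                   "receptor-head", "counterion")
  if (!all(df$role %in% valid_roles)) {
    stop("unknown bead role: ", paste(setdiff(df$role, valid_roles), collapse = ", "))
  }
  if (any(df$mass <= 0 & !df$frozen)) stop("mobile beads need mass > 0")
  if (any(df$radius <= 0)) stop("radius must be > 0")
  if (any(df$frozen & !df$role %in% c("receptor-base", "receptor-head"))) {
    stop("only receptor-base or receptor-head beads may be frozen")
  }
  df
}

#' Default bead type registry
#'
#' The standard taxonomy used by the builders: single-bead monomers and
#' guests plus mono-bead frozen receptors for the minimalistic model, and
#' core/tail/charged-head oligomer beads, three-bead tethered receptors and
#' counterions for the oligomer (micelle) model.
#'
#' @return a bead type `data.frame`.
#' @export
default_bead_types <- function() {
  rbind(
    bead_types("M",    role = "monomer",               radius = 0.335),
    bead_types("G",    role = "guest",                 radius = 0.315),
    bead_types("R",    role = "receptor-head",         radius = 0.275, frozen = TRUE),
    bead_types("C",    role = "oligomer-core",         radius = 0.335),
    bead_types("T",    role = "oligomer-tail",         radius = 0.335),
    bead_types("H",    role = "oligomer-head-charged", radius = 0.335, charge = -1),
    bead_types("HN",   role = "oligomer-head-neutral", radius = 0.335),
    bead_types("RB",   role = "receptor-base",         radius = 0.335, frozen = TRUE),
    bead_types("RL",   role = "receptor-linker",       radius = 0.335),
    bead_types("RH",   role = "receptor-head",         radius = 0.335, charge = +1),
    bead_types("ION",  role = "counterion",            radius = 0.235, charge = +1),
    bead_types("IONM", role = "counterion",            radius = 0.235, charge = -1)
  )
}

#' Construct a simulation system
#'
#' @param pos N x 3 matrix of positions, nm.
#' @param type integer vector (index into `types$name`) or character vector
#'   of type names.
#' @param types bead type table ([bead_types()]); defaults to
#'   [default_bead_types()].
#' @param vel N x 3 velocities, nm/ps; zero if omitted.
#' @param bonds matrix with columns (i, j, r0, k): harmonic bonds,
#'   r0 in nm, k in kJ mol^-1 nm^-2. 1-based indices.
#' @param angles matrix with columns (i, j, k, theta0, ktheta): harmonic
#'   angles about j, theta0 in radians, ktheta in kJ mol^-1 rad^-2.
#' @param groups named list of integer index vectors.
#' @param box length-3 numeric (lx, ly, lz), nm.
#' @param periodic length-3 logical; default periodic in x and y only.
#' @param time simulation time, ps.
#' @param charge optional explicit per-bead charges (e), overriding the
#'   type-table values (e.g. configurable receptor head charge).
#' @return an object of class `cg_system`.
#' @export
cg_system <- function(pos, type, types = default_bead_types(), vel = NULL,
                      bonds = NULL, angles = NULL, groups = list(),
                      box = c(10, 10, 10), periodic = c(TRUE, TRUE, FALSE),
                      time = 0, charge = NULL) {
  pos <- as.matrix(pos)
  if (ncol(pos) != 3) stop("pos must be N x 3")
  n <- nrow(pos)
  if (is.character(type)) {
    idx <- match(type, types$name)
    if (anyNA(idx)) stop("unknown bead type: ", paste(unique(type[is.na(idx)]), collapse = ", "))
    type <- idx
  }
  type <- as.integer(type)
  if (length(type) != n) stop("type length must match bead count")
  if (any(type < 1L | type > nrow(types))) stop("type index out of range")
  if (is.null(vel)) vel <- matrix(0, n, 3)
  frozen <- types$frozen[type]
  vel[frozen, ] <- 0
  if (!is.null(bonds)) {
    bonds <- as.matrix(bonds)
    stopifnot(ncol(bonds) == 4)
  }
  if (!is.null(angles)) {
    angles <- as.matrix(angles)
    stopifnot(ncol(angles) == 5)
  }
  for (g in groups) {
    if (length(g) && (min(g) < 1 || max(g) > n)) stop("group index out of range")
  }
  if (is.null(charge)) charge <- types$charge[type]
  if (length(charge) != n) stop("charge length must match bead count")
  structure(list(
    pos = unname(pos), vel = unname(as.matrix(vel)),
    type = type, types = types,
    mass = types$mass[type], charge = as.numeric(charge),
    frozen = frozen,
    bonds = bonds, angles = angles, groups = groups,
    box = as.numeric(box), periodic = as.logical(periodic),
    time = time
  ), class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat("<cg_system>", nrow(x$pos), "beads |",
      sum(!x$frozen), "mobile |",
      if (is.null(x$bonds)) 0 else nrow(x$bonds), "bonds |",
      "net charge", sprintf("%+.0f e", sum(x$charge)), "\n")
  cat("  box:", paste(sprintf("%.2f", x$box), collapse = " x "), "nm ;",
      "periodic:", paste(ifelse(x$periodic, "x", "-")[1],
                         ifelse(x$periodic, "y", "-")[2],
                         ifelse(x$periodic, "z", "-")[3]), "\n")
  if (length(x$groups)) {
    cat("  groups:", paste(sprintf("%s[%d]", names(x$groups),
                                   lengths(x$groups)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of beads in a system
#' @param system a `cg_system`.
#' @return integer bead count.
#' @export
n_beads <- function(system) nrow(system$pos)

#' Total charge of a system
#' @param system a `cg_system`.
#' @return total charge in e.
#' @export
total_charge <- function(system) sum(system$charge)

#' Merge two system fragments
#'
#' Concatenates beads; bond/angle/group indices of `b` are shifted. The box
#' and periodicity are taken from `a` unless `b`'s box is larger in any
#' dimension, in which case the union (elementwise max) is used. Both
#' fragments must use the same bead-type table.
#'
#' @param a,b `cg_system` fragments.
#' @return merged `cg_system`.
#' @export
merge_systems <- function(a, b) {
  if (!identical(a$types$name, b$types$name)) {
    stop("fragments use different bead-type tables")
  }
  na <- nrow(a$pos)
  shift <- function(m, cols) {
    if (is.null(m)) return(NULL)
    m[, cols] <- m[, cols] + na
    m
  }
  bonds <- rbind(a$bonds, shift(b$bonds, 1:2))
  angles <- rbind(a$angles, shift(b$angles, 1:3))
  groups <- a$groups
  for (nm in names(b$groups)) {
    groups[[nm]] <- c(groups[[nm]], b$groups[[nm]] + na)
  }
  out <- cg_system(rbind(a$pos, b$pos), c(a$type, b$type), types = a$types,
                   vel = rbind(a$vel, b$vel), bonds = bonds, angles = angles,
                   groups = groups, box = pmax(a$box, b$box),
                   periodic = a$periodic, time = a$time,
                   charge = c(a$charge, b$charge))
  out$meta <- c(a$meta, b$meta)
  out
}

#' Look up a bead group
#'
#' @param system a `cg_system`.
#' @param group group name or integer index vector.
#' @return integer vector of bead indices.
#' @export
get_group <- function(system, group) {
  if (is.character(group)) {
    if (!group %in% names(system$groups)) stop("no such group: ", group)
    g <- system$groups[[group]]
  } else {
    g <- as.integer(group)
  }
  if (!length(g)) stop("empty bead group")
  g
}

#' Center of mass of a bead group
#'
#' @param system a `cg_system`.
#' @param group group name or index vector.
#' @return length-3 numeric, nm.
#' @export
center_of_mass <- function(system, group) {
  g <- get_group(system, group)
  m <- system$mass[g]
  colSums(system$pos[g, , drop = FALSE] * m) / sum(m)
}

# round half away from zero (receptor-count convention; R's round() is
# round-half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
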