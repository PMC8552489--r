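# Deterministic, seeded construction of nanoparticles, guests, receptor
# surfaces, counterions and assembled simulation systems.

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FCC lattice points with nearest-neighbor distance `a`, sorted by distance
# from the origin, at least n of them
fcc_points <- function(n, a, rmax = NULL) {
  # cubic FCC cell edge: a*sqrt(2); basis of 4 points
  cell <- a * sqrt(2)
  k <- 1
  repeat {
    g <- seq(-k, k)
    grid <- expand.grid(i = g, j = g, l = g)
    base <- as.matrix(grid) * cell
    basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5)) * cell
    pts <- do.call(rbind, lapply(seq_len(4), function(b) sweep(base, 2, basis[b, ], "+")))
    d <- sqrt(rowSums(pts^2))
    o <- order(d)
    pts <- pts[o, , drop = FALSE]
    d <- d[o]
    if (!is.null(rmax)) {
      keep <- d <= rmax
      if (sum(keep) >= n || k > 40) return(pts[keep, , drop = FALSE])
    } else if (nrow(pts) >= n && d[n] < k * cell * 0.8) {
      return(pts[seq_len(n), , drop = FALSE])
    }
    k <- k + 1
    if (k > 60) stop("lattice generation failed")
  }
}

# quasi-uniform directions on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

check_min_separation <- function(pos, min_sep) {
  if (nrow(pos) < 2) return(TRUE)
  min(stats::dist(pos)) >= min_sep
}

#' Build a single-bead-per-monomer nanoparticle
#'
#' Places monomer beads on a jittered FCC lattice filling a sphere, with
#' guest beads occupying the innermost lattice sites (interior to the
#' monomer shell). Construction is deterministic under a fixed seed. The
#' lattice spacing is the monomer LJ minimum (2^(1/6) sigma_mm), so the
#' cluster starts near its energy-minimum packing.
#'
#' @param n_monomers number of monomer beads (>= 1).
#' @param n_guests number of encapsulated guest beads (default 0).
#' @param packing_radius optional sphere radius, nm; by default just large
#'   enough for the requested bead count. Too small a radius for the count
#'   is an error (infeasible density).
#' @param seed integer RNG seed for the lattice jitter.
#' @param sigma_mm monomer LJ sigma, nm (default 0.47); sets the lattice
#'   spacing.
#' @param jitter jitter amplitude as a fraction of the lattice spacing
#'   (default 0.04).
#' @return a `cg_system` fragment with groups `monomer_beads`,
#'   `guest_beads`, `np_beads`, centered so the fragment COM is the origin.
#' @export
build_nanoparticle_mcg <- function(n_monomers, n_guests = 0,
                                   packing_radius = NULL, seed = 1,
                                   sigma_mm = 0.47, jitter = 0.04) {
  stopifnot(n_monomers >= 1, n_guests >= 0)
  n <- n_monomers + n_guests
  a <- 2^(1 / 6) * sigma_mm
  if (!is.null(packing_radius)) {
    pts <- fcc_points(n, a, rmax = packing_radius)
    if (nrow(pts) < n) {
      stop("infeasible density: packing_radius holds only ", nrow(pts),
           " lattice sites for ", n, " beads")
    }
    pts <- pts[seq_len(n), , drop = FALSE]
  } else {
    pts <- fcc_points(n, a)
  }
  min_sigma <- if (n_guests > 0) 0.43 else sigma_mm
  pos <- NULL
  with_seed(seed, {
    for (try in 1:5) {
      jig <- matrix(runif(3 * n, -jitter, jitter) * a, n, 3)
      cand <- pts + jig
      if (check_min_separation(cand, 0.9 * min_sigma)) {
        pos <- cand
        break
      }
      jitter <- jitter / 2
    }
  })
  if (is.null(pos)) stop("packing failure: could not jitter without overlap")
  pos <- sweep(pos, 2, colMeans(pos))  # COM at origin (equal masses)
  # innermost sites -> guests
  ord <- order(sqrt(rowSums(pos^2)))
  type <- character(n)
  guest_idx <- ord[seq_len(n_guests)]
  type[guest_idx] <- "G"
  type[setdiff(seq_len(n), guest_idx)] <- "M"
  ext <- max(sqrt(rowSums(pos^2))) + 2
  sys <- cg_system(pos, type, box = rep(2 * ext, 3))
  sys$groups <- list(monomer_beads = which(type == "M"),
                     guest_beads = which(type == "G"),
                     np_beads = seq_len(n))
  sys
}

#' Oligomer template
#'
#' A branched amphiphile: one core bead, `n_tails` hydrophobic tails of
#' `tail_length` beads each, and `n_heads` hydrophilic head beads attached
#' to the core, of which the first `n_charged_heads` carry -1 e (the rest
#' are neutral). Mono-, di- and trivalent oligomers therefore share one
#' scaffold and differ only in charge, so valence comparisons are not
#' confounded by bead count. The connectivity is a tree (connected,
#' acyclic) and the net charge is -`n_charged_heads` e.
#'
#' @param n_tails number of hydrophobic tails (default 3).
#' @param tail_length beads per tail (default 2).
#' @param n_charged_heads charged head beads, 1-3 (default 3: trivalent).
#' @param n_heads total hydrophilic head beads (default 3; must be >=
#'   `n_charged_heads`).
#' @param bond_r0 bond length, nm (default 0.47).
#' @param bond_k bond force constant, kJ mol^-1 nm^-2 (default 1250).
#' @param angle_k tail-straightening angle constant, kJ mol^-1 rad^-2
#'   (default 25; theta0 = 180 deg along each tail).
#' @return an `oligomer_template` list with per-bead types/charges and
#'   local bond/angle tables.
#' @export
oligomer_template <- function(n_tails = 3, tail_length = 2,
                              n_charged_heads = 3, n_heads = 3,
                              bond_r0 = 0.47, bond_k = 1250, angle_k = 25) {
  stopifnot(n_tails >= 1, tail_length >= 1, n_charged_heads %in% 1:3,
            n_heads >= n_charged_heads)
  type <- "C"
  bonds <- NULL
  angles <- NULL
  for (t in seq_len(n_tails)) {
    prev <- 1L  # core
    for (b in seq_len(tail_length)) {
      type <- c(type, "T")
      cur <- length(type)
      bonds <- rbind(bonds, c(prev, cur, bond_r0, bond_k))
      if (b >= 2) {
        pp <- bonds[nrow(bonds) - 1, 1]
        angles <- rbind(angles, c(pp, prev, cur, pi, angle_k))
      }
      prev <- cur
    }
  }
  head_idx <- integer(0)
  for (h in seq_len(n_heads)) {
    type <- c(type, if (h <= n_charged_heads) "H" else "HN")
    head_idx <- c(head_idx, length(type))
    bonds <- rbind(bonds, c(1L, length(type), bond_r0, bond_k))
  }
  # head-core-head spreading angles keep branches from collapsing (their
  # 1-3 nonbonded pairs are excluded)
  if (length(head_idx) > 1) {
    for (i in seq_len(length(head_idx) - 1)) {
      for (j in seq.int(i + 1, length(head_idx))) {
        angles <- rbind(angles,
                        c(head_idx[i], 1L, head_idx[j], 109.5 * pi / 180, 25))
      }
    }
  }
  # first tail beads fan out from the core the same way
  first_tail <- 1L + (seq_len(n_tails) - 1L) * tail_length + 1L
  if (n_tails > 1) {
    for (i in seq_len(n_tails - 1)) {
      for (j in seq.int(i + 1, n_tails)) {
        angles <- rbind(angles,
                        c(first_tail[i], 1L, first_tail[j],
                          109.5 * pi / 180, 25))
      }
    }
  }
  # heads (outward) vs first tail beads (inward): keep opposite sides of
  # the core so these excluded 1-3 branches cannot fold onto each other
  for (h in head_idx) {
    for (ft in first_tail) {
      angles <- rbind(angles, c(h, 1L, ft, 140 * pi / 180, 15))
    }
  }
  structure(list(type = type, n_beads = length(type),
                 n_tails = n_tails, tail_length = tail_length,
                 n_charged_heads = n_charged_heads, n_heads = n_heads,
                 bonds = bonds, angles = angles),
            class = "oligomer_template")
}

# unit vectors orthogonal to u
tangent_frame <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Build a micelle-like oligomer nanoparticle
#'
#' Assembles `n_oligomers` copies of an amphiphilic oligomer template into
#' a micelle: cores on a sphere, hydrophobic tails pointing inward, charged
#' heads outward, guest beads in the interior. A short builder-internal
#' damped relaxation removes residual overlaps (deterministic).
#'
#' @param template an [oligomer_template()].
#' @param n_oligomers number of oligomers (>= 1).
#' @param n_guests encapsulated guest beads (default 0).
#' @param seed integer RNG seed.
#' @param relax logical; run the internal steepest-descent relaxation
#'   (default TRUE).
#' @param pt pair table used for the relaxation (default
#'   [fcg_pair_table()]).
#' @return a `cg_system` fragment with groups `np_beads`,
#'   `np_charged_beads`, `guest_beads`, `core_beads`, `tail_beads` and a
#'   `meta$oligomer_id` per-bead index.
#' @export
build_nanoparticle_fcg <- function(template = oligomer_template(),
                                   n_oligomers, n_guests = 0, seed = 1,
                                   relax = TRUE, pt = fcg_pair_table()) {
  stopifnot(n_oligomers >= 1, n_guests >= 0)
  d0 <- 0.47
  # core shell radius: ~1.1 nm of sphere surface per oligomer, min 0.9 nm
  rc <- max(0.9, sqrt(n_oligomers * 1.1^2 / (4 * pi)))
  dirs <- fibonacci_sphere(n_oligomers)
  pos <- NULL
  type <- character(0)
  bonds <- NULL
  angles <- NULL
  olig_id <- integer(0)
  jit <- with_seed(seed, matrix(runif(3 * n_oligomers * template$n_beads,
                                      -0.03, 0.03), ncol = 3))
  jrow <- 0
  for (k in seq_len(n_oligomers)) {
    u <- dirs[k, ]
    fr <- tangent_frame(u)
    local_pos <- matrix(0, template$n_beads, 3)
    local_pos[1, ] <- rc * u  # core
    bead <- 1L
    for (t in seq_len(template$n_tails)) {
      # tails fan slightly off the inward radial direction
      ang <- 2 * pi * (t - 1) / template$n_tails
      tan_dir <- cos(ang) * fr$e1 + sin(ang) * fr$e2
      dir_in <- -u + 0.45 * tan_dir
      dir_in <- dir_in / sqrt(sum(dir_in^2))
      for (b in seq_len(template$tail_length)) {
        bead <- bead + 1L
        local_pos[bead, ] <- rc * u + dir_in * d0 * b
      }
    }
    n_hd <- template$n_heads %||% template$n_charged_heads
    for (h in seq_len(n_hd)) {
      ang <- 2 * pi * (h - 1) / max(1, n_hd)
      tan_dir <- cos(ang) * fr$e1 + sin(ang) * fr$e2
      dir_out <- u + 0.5 * tan_dir
      dir_out <- dir_out / sqrt(sum(dir_out^2))
      bead <- bead + 1L
      local_pos[bead, ] <- rc * u + dir_out * d0
    }
    local_pos <- local_pos + jit[jrow + seq_len(template$n_beads), ]
    jrow <- jrow + template$n_beads
    off <- length(type)
    pos <- rbind(pos, local_pos)
    type <- c(type, template$type)
    olig_id <- c(olig_id, rep(k, template$n_beads))
    if (!is.null(template$bonds)) {
      b2 <- template$bonds
      b2[, 1:2] <- b2[, 1:2] + off
      bonds <- rbind(bonds, b2)
    }
    if (!is.null(template$angles)) {
      a2 <- template$angles
      a2[, 1:3] <- a2[, 1:3] + off
      angles <- rbind(angles, a2)
    }
  }
  if (n_guests > 0) {
    gp <- fcc_points(n_guests, 0.48)
    gp <- sweep(gp, 2, colMeans(gp))
    pos <- rbind(pos, gp)
    type <- c(type, rep("G", n_guests))
    olig_id <- c(olig_id, rep(0L, n_guests))
  }
  n <- nrow(pos)
  ext <- max(sqrt(rowSums(pos^2))) + 3
  sys <- cg_system(pos, type, bonds = bonds, angles = angles,
                   box = rep(2 * ext, 3), periodic = c(FALSE, FALSE, FALSE))
  np_idx <- which(olig_id > 0)
  sys$groups <- list(
    np_beads = np_idx,
    np_charged_beads = which(type == "H"),
    head_beads = which(type %in% c("H", "HN")),
    guest_beads = which(type == "G"),
    core_beads = which(type == "C"),
    tail_beads = which(type == "T")
  )
  sys$meta <- list(oligomer_id = olig_id)
  if (relax && n > 1) {
    ff <- build_ff_list(sys, pt)
    sys$pos <- minimize_cpp(unclass(sys), ff, max_steps = 300,
                            fmax_tol = 50, step0 = 0.005)
    sys$pos <- sweep(sys$pos, 2, center_of_mass(sys, seq_len(n)))
  }
  sys
}

#' Surface specification
#'
#' Rectangular receptor regions tiling an lx x ly surface, each with a
#' target receptor density. The realized receptor count per region is
#' round(area x rho) (half away from zero), so density ratios between
#' regions are exact whenever the products are integral.
#'
#' @param lx,ly surface extent, nm.
#' @param regions data.frame with columns `x0`, `x1`, `y0`, `y1`, `rho`
#'   (receptors per nm^2).
#' @param receptor_model `"monobead_frozen"` (single frozen bead) or
#'   `"tribead_tethered"` (frozen base, harmonic linker, charged head).
#' @param placement `"lattice"` (exact grid) or `"poisson_disc"` (seeded
#'   dart throwing with minimum separation 1/sqrt(2 rho)).
#' @param head_charge receptor head charge, e (default +1 for tethered
#'   receptors, 0 for monobead).
#' @return a `surface_spec` object.
#' @export
surface_spec <- function(lx, ly, regions,
                         receptor_model = c("monobead_frozen", "tribead_tethered"),
                         placement = c("poisson_disc", "lattice"),
                         head_charge = NULL) {
  receptor_model <- match.arg(receptor_model)
  placement <- match.arg(placement)
  if (is.null(head_charge)) {
    head_charge <- if (receptor_model == "tribead_tethered") 1 else 0
  }
  regions <- as.data.frame(regions)
  stopifnot(all(c("x0", "x1", "y0", "y1", "rho") %in% names(regions)))
  if (any(regions$rho < 0)) stop("densities must be >= 0")
  areas <- (regions$x1 - regions$x0) * (regions$y1 - regions$y0)
  if (any(areas <= 0)) stop("degenerate region")
  nr <- nrow(regions)
  if (nr > 1) {
    for (i in seq_len(nr - 1)) for (j in seq(i + 1, nr)) {
      ox <- min(regions$x1[i], regions$x1[j]) - max(regions$x0[i], regions$x0[j])
      oy <- min(regions$y1[i], regions$y1[j]) - max(regions$y0[i], regions$y0[j])
      if (ox > 1e-9 && oy > 1e-9) stop("regions overlap")
    }
  }
  if (abs(sum(areas) - lx * ly) > 1e-9 * lx * ly) {
    stop("regions must tile the surface exactly")
  }
  structure(list(lx = lx, ly = ly, regions = regions,
                 receptor_model = receptor_model, placement = placement,
                 head_charge = head_charge),
            class = "surface_spec")
}

#' Two-region surface specification
#'
#' Two equal-area regions split along x: the low-density half
#' (x < lx/2, rho = rho_high x ratio) and the high-density half
#' (x >= lx/2, rho = rho_high).
#'
#' @param lx,ly surface extent, nm.
#' @param rho_high receptor density of the dense half, nm^-2.
#' @param ratio low/high density ratio in (0, 1].
#' @param ... passed to [surface_spec()].
#' @return a `surface_spec`.
#' @export
two_region_spec <- function(lx, ly, rho_high, ratio, ...) {
  stopifnot(ratio > 0, ratio <= 1, rho_high >= 0)
  regions <- data.frame(
    x0 = c(0, lx / 2), x1 = c(lx / 2, lx), y0 = 0, y1 = ly,
    rho = c(rho_high * ratio, rho_high))
  surface_spec(lx, ly, regions, ...)
}

#' Gradient-stripe surface specification
#'
#' Consecutive equal-width stripes along x with the given receptor
#' densities (a receptor-density gradient for rolling experiments).
#'
#' @param stripe_densities receptor densities per stripe, nm^-2.
#' @param stripe_lx stripe width along x, nm.
#' @param ly surface depth, nm.
#' @param ... passed to [surface_spec()]; the default receptor model for
#'   stripes is `"tribead_tethered"`.
#' @return a `surface_spec` of total size
#'   `length(stripe_densities) * stripe_lx` x `ly`.
#' @export
gradient_stripes_spec <- function(stripe_densities, stripe_lx, ly,
                                  receptor_model = "tribead_tethered", ...) {
  ns <- length(stripe_densities)
  stopifnot(ns >= 1)
  regions <- data.frame(
    x0 = (seq_len(ns) - 1) * stripe_lx, x1 = seq_len(ns) * stripe_lx,
    y0 = 0, y1 = ly, rho = stripe_densities)
  surface_spec(ns * stripe_lx, ly, regions, receptor_model = receptor_model, ...)
}

# seeded dart-throwing with minimum separation (also against receptors
# already placed in other regions, so stripe boundaries stay clean);
# exact count or error
poisson_disc_points <- function(n, x0, x1, y0, y1, min_sep, existing = NULL) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  pts <- matrix(NA_real_, n, 2)
  got <- 0
  tries <- 0
  max_tries <- 500 * n
  ok_against <- function(p, mat, sep) {
    is.null(mat) || nrow(mat) == 0 ||
      min((mat[, 1] - p[1])^2 + (mat[, 2] - p[2])^2) >= sep^2
  }
  while (got < n && tries < max_tries) {
    tries <- tries + 1
    p <- c(runif(1, x0, x1), runif(1, y0, y1))
    if (ok_against(p, pts[seq_len(got), , drop = FALSE], min_sep) &&
        ok_against(p, existing, min_sep)) {
      got <- got + 1
      pts[got, ] <- p
    }
  }
  if (got < n) {
    stop("infeasible spec: density too high for poisson_disc minimum separation")
  }
  pts
}

lattice_points <- function(n, x0, x1, y0, y1) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  w <- x1 - x0
  h <- y1 - y0
  nx <- max(1, ceiling(sqrt(n * w / h)))
  ny <- ceiling(n / nx)
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  g <- g[seq_len(n), ]
  cbind(x0 + (g$i - 0.5) * w / nx, y0 + (g$j - 0.5) * h / ny)
}

#' Build a receptor surface
#'
#' Realizes a [surface_spec()]: each region receives round(area x rho)
#' receptors (half away from zero). Mono-bead receptors are single frozen
#' beads in the z = 0 plane; tethered receptors are vertical three-bead
#' chains (frozen base at z = 0, harmonic linker, charged head at
#' ~0.7 nm) with a straightening angle.
#'
#' @param spec a `surface_spec`.
#' @param seed integer RNG seed (poisson_disc placement).
#' @param lz box height, nm (default 12).
#' @return a `cg_system` fragment with groups `receptor_heads` and
#'   `receptor_beads`, plus `meta$region_counts`.
#' @export
build_surface <- function(spec, seed = 1, lz = 12) {
  stopifnot(inherits(spec, "surface_spec"))
  xy <- NULL
  counts <- integer(nrow(spec$regions))
  with_seed(seed, {
    for (r in seq_len(nrow(spec$regions))) {
      rg <- spec$regions[r, ]
      area <- (rg$x1 - rg$x0) * (rg$y1 - rg$y0)
      nrec <- as.integer(round_half_away(area * rg$rho))
      counts[r] <- nrec
      if (nrec == 0) next
      pts <- if (spec$placement == "lattice") {
        lattice_points(nrec, rg$x0, rg$x1, rg$y0, rg$y1)
      } else {
        poisson_disc_points(nrec, rg$x0, rg$x1, rg$y0, rg$y1,
                            min_sep = min(1 / sqrt(2 * rg$rho), 2),
                            existing = xy)
      }
      xy <- rbind(xy, pts)
    }
  })
  nrec <- if (is.null(xy)) 0L else nrow(xy)
  if (spec$receptor_model == "monobead_frozen") {
    if (nrec == 0) {
      pos <- matrix(numeric(0), 0, 3)
      type <- character(0)
      charge <- numeric(0)
    } else {
      pos <- cbind(xy, 0)
      type <- rep("R", nrec)
      charge <- rep(spec$head_charge, nrec)
    }
    sys <- cg_system(pos, type, box = c(spec$lx, spec$ly, lz), charge = charge)
    sys$groups <- list(receptor_heads = seq_len(nrec),
                       receptor_beads = seq_len(nrec))
  } else {
    pos <- matrix(numeric(0), 0, 3)
    type <- character(0)
    bonds <- NULL
    angles <- NULL
    for (i in seq_len(nrec)) {
      b <- 3 * (i - 1)
      pos <- rbind(pos,
                   c(xy[i, ], 0), c(xy[i, ], 0.35), c(xy[i, ], 0.70))
      type <- c(type, "RB", "RL", "RH")
      bonds <- rbind(bonds,
                     c(b + 1, b + 2, 0.35, 5000),
                     c(b + 2, b + 3, 0.35, 5000))
      angles <- rbind(angles, c(b + 1, b + 2, b + 3, pi, 50))
    }
    charge <- rep(c(0, 0, spec$head_charge), nrec)
    sys <- cg_system(pos, type, bonds = bonds, angles = angles,
                     box = c(spec$lx, spec$ly, lz), charge = charge)
    sys$groups <- list(receptor_heads = which(type == "RH"),
                       receptor_beads = seq_along(type))
  }
  sys$meta <- list(region_counts = counts, surface_spec = spec)
  sys
}

#' Realized receptor densities per region
#'
#' @param surface a surface fragment from [build_surface()].
#' @return data.frame with target `rho`, realized count and realized
#'   density per region.
#' @export
realized_densities <- function(surface) {
  spec <- surface$meta$surface_spec
  counts <- surface$meta$region_counts
  areas <- (spec$regions$x1 - spec$regions$x0) *
    (spec$regions$y1 - spec$regions$y0)
  data.frame(rho_target = spec$regions$rho, count = counts,
             area = areas, rho_realized = counts / areas)
}

#' Assemble a nanoparticle above a surface
#'
#' Shifts the nanoparticle fragment so its COM sits at
#' (lx/2, ly/2, z_offset) over the surface, merges the fragments, and
#' optionally adds +1 e counterion beads at seeded random non-overlapping
#' positions until the total system charge is exactly zero.
#'
#' @param np nanoparticle fragment.
#' @param surface surface fragment (defines the box footprint).
#' @param z_offset height of the NP center of mass above the surface
#'   plane, nm; by default half the NP z-extent plus 1.5 nm.
#' @param xy in-plane COM target (lx/2, ly/2 by default), nm.
#' @param neutralize logical; add counterions (default TRUE).
#' @param seed integer RNG seed for counterion placement.
#' @param lz box height, nm; enlarged automatically if the NP needs room.
#' @return the merged `cg_system` (group `counterions` added when ions are
#'   placed).
#' @export
assemble_system <- function(np, surface, z_offset = NULL, xy = NULL,
                            neutralize = TRUE, seed = 1, lz = NULL) {
  ext_z <- diff(range(np$pos[, 3]))
  if (is.null(z_offset)) z_offset <- ext_z / 2 + 1.5
  if (is.null(lz)) lz <- max(surface$box[3], z_offset + ext_z / 2 + 4)
  if (is.null(xy)) xy <- c(surface$box[1] / 2, surface$box[2] / 2)
  np2 <- np
  target <- c(xy[1], xy[2], z_offset)
  shift <- target - center_of_mass(np, seq_len(n_beads(np)))
  np2$pos <- sweep(np2$pos, 2, shift, "+")
  np2$box <- c(surface$box[1], surface$box[2], lz)
  np2$periodic <- surface$periodic
  surface$box[3] <- lz
  sys <- merge_systems(surface, np2)
  # overlap check between fragments
  ns <- n_beads(surface)
  if (ns > 0 && n_beads(np2) > 0) {
    dmin <- min(cross_min_dist(surface$pos, np2$pos))
    if (dmin < 0.9 * 0.35) {
      stop("bad z_offset: nanoparticle overlaps the surface (min dist ",
           round(dmin, 3), " nm)")
    }
  }
  if (neutralize) {
    q <- sum(sys$charge)
    n_ion <- as.integer(round_half_away(abs(q)))
    if (n_ion > 0) {
      ion_type <- if (q < 0) "ION" else "IONM"  # +1 e or -1 e counterions
      ion_pos <- with_seed(seed + 7L, place_ions(sys, n_ion, lz))
      ion <- cg_system(ion_pos, rep(ion_type, n_ion), types = sys$types,
                       box = sys$box, periodic = sys$periodic)
      ion$groups <- list(counterions = seq_len(n_ion))
      sys <- merge_systems(sys, ion)
    }
  }
  sys
}

cross_min_dist <- function(a, b) {
  # min distance from each row of b to any row of a
  out <- numeric(nrow(b))
  for (i in seq_len(nrow(b))) {
    d <- sweep(a, 2, b[i, ])
    out[i] <- sqrt(min(rowSums(d * d)))
  }
  out
}

place_ions <- function(sys, n_ion, lz) {
  out <- matrix(NA_real_, n_ion, 3)
  got <- 0
  tries <- 0
  occupied <- sys$pos
  while (got < n_ion && tries < 2000 * n_ion) {
    tries <- tries + 1
    p <- c(runif(1, 0, sys$box[1]), runif(1, 0, sys$box[2]),
           runif(1, 0.8, lz - 0.8))
    d2 <- min(rowSums(sweep(occupied, 2, p)^2))
    if (d2 >= 0.45^2) {
      got <- got + 1
      out[got, ] <- p
      occupied <- rbind(occupied, p)
    }
  }
  if (got < n_ion) stop("could not place counterions without overlap")
  out
}
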