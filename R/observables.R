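# Trajectory analysis: engagement/contacts, Shrake-Rupley SASA and
# percent SASA change, guest release, MSD / drift velocity, and surface
# region occupancy.

#' Multivalent engagement count
#'
#' Number of NP charged beads having at least one receptor head within the
#' cutoff. This per-bead counter saturates at the NP charged-bead count
#' (e.g. 132 for a 44-oligomer trivalent NP), unlike the raw pair-contact
#' count which can exceed it.
#'
#' @param system a `cg_system`.
#' @param np_charged,receptor_heads group names or index vectors.
#' @param cutoff contact cutoff, nm (default 0.6).
#' @return integer engagement count (<= |np_charged|).
#' @export
engagement_count <- function(system, np_charged = "np_charged_beads",
                             receptor_heads = "receptor_heads",
                             cutoff = 0.6) {
  ga <- get_group(system, np_charged)
  gb <- get_group(system, receptor_heads)
  cnt <- count_within_cpp(system$pos[ga, , drop = FALSE],
                          system$pos[gb, , drop = FALSE], cutoff)
  sum(cnt >= 1L)
}

#' Raw charged-bead/receptor pair contacts
#'
#' @inheritParams engagement_count
#' @return integer number of A-B pairs within the cutoff.
#' @export
pair_contact_count <- function(system, np_charged = "np_charged_beads",
                               receptor_heads = "receptor_heads",
                               cutoff = 0.6) {
  ga <- get_group(system, np_charged)
  gb <- get_group(system, receptor_heads)
  sum(count_within_cpp(system$pos[ga, , drop = FALSE],
                       system$pos[gb, , drop = FALSE], cutoff))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA over a bead group with Fibonacci-distributed sphere
#' points. Default bead radii are sigma/2 + 0.1 nm per type (stored in the
#' type table); the default probe is 0.19 nm.
#'
#' @param system a `cg_system`.
#' @param group group name or index vector (default the NP beads).
#' @param probe probe radius, nm.
#' @param n_sphere_points points per bead sphere (default 240).
#' @param radii optional per-bead radii override, nm.
#' @return total SASA, nm^2.
#' @export
sasa <- function(system, group = "np_beads", probe = 0.19,
                 n_sphere_points = 240, radii = NULL) {
  g <- get_group(system, group)
  r <- if (is.null(radii)) system$types$radius[system$type[g]] else
    rep_len(radii, length(g))
  if (any(r <= 0)) stop("radii must be > 0")
  sum(sasa_cpp(system$pos[g, , drop = FALSE], r, probe,
               as.integer(n_sphere_points)))
}

#' SASA series over a trajectory
#'
#' @inheritParams sasa
#' @param traj a `cg_trajectory`.
#' @return data.frame (time, sasa).
#' @export
sasa_series <- function(traj, group = "np_beads", probe = 0.19,
                        n_sphere_points = 240) {
  sys <- traj$final_system
  g <- get_group(sys, group)
  r <- sys$types$radius[sys$type[g]]
  vals <- vapply(traj$frames, function(p) {
    sum(sasa_cpp(p[g, , drop = FALSE], r, probe, as.integer(n_sphere_points)))
  }, numeric(1))
  data.frame(time = traj$times, sasa = vals)
}

#' Percent SASA change relative to a reference frame
#'
#' 100 (SASA(t) - SASA_ref) / SASA_ref; positive values signal NP
#' deformation / exfoliation. The reference defaults to the first frame of
#' the series.
#'
#' @param sasa_series data.frame (time, sasa) from [sasa_series()], or a
#'   numeric vector.
#' @param reference reference SASA (nm^2) or reference frame index
#'   (default 1).
#' @return data.frame (time, delta_sasa_pct) or numeric vector.
#' @export
delta_sasa_percent <- function(sasa_series, reference = 1L) {
  v <- if (is.data.frame(sasa_series)) sasa_series$sasa else
    as.numeric(sasa_series)
  ref <- if (length(reference) == 1 && reference == round(reference) &&
             reference >= 1 && reference <= length(v)) v[reference] else
    as.numeric(reference)
  if (ref <= 0) stop("reference SASA must be > 0")
  pct <- 100 * (v - ref) / ref
  if (is.data.frame(sasa_series)) {
    data.frame(time = sasa_series$time, delta_sasa_pct = pct)
  } else pct
}

#' Guest release report
#'
#' A guest is released at the first time its contact count with the
#' monomer/oligomer group stays zero for `persistence` consecutive frames
#' (suppressing transient detachments); the cumulative release fraction is
#' non-decreasing by construction.
#'
#' @param traj a `cg_trajectory`.
#' @param guests,np group names or index vectors.
#' @param cutoff contact cutoff, nm (default 0.6).
#' @param persistence consecutive zero-contact frames required (default
#'   10; capped at the frame count).
#' @return a `release_report`: per-guest release time (NA = censored),
#'   `series` (time, release_pct) and `final_pct`.
#' @export
guest_release <- function(traj, guests = "guest_beads", np = "np_beads",
                          cutoff = 0.6, persistence = 10L) {
  sys <- traj$final_system
  gg <- get_group(sys, guests)
  gn <- setdiff(get_group(sys, np), gg)
  nf <- length(traj$frames)
  persistence <- min(as.integer(persistence), nf)
  contacts <- vapply(traj$frames, function(p) {
    count_within_cpp(p[gg, , drop = FALSE], p[gn, , drop = FALSE], cutoff)
  }, integer(length(gg)))
  contacts <- matrix(contacts, nrow = length(gg))  # guests x frames
  release_frame <- rep(NA_integer_, length(gg))
  for (i in seq_along(gg)) {
    zero <- contacts[i, ] == 0L
    run <- 0L
    for (f in seq_len(nf)) {
      run <- if (zero[f]) run + 1L else 0L
      if (run >= persistence) {
        release_frame[i] <- f - persistence + 1L
        break
      }
    }
  }
  released_by <- vapply(seq_len(nf), function(f) {
    sum(!is.na(release_frame) & release_frame + persistence - 1L <= f)
  }, integer(1))
  series <- data.frame(time = traj$times,
                       release_pct = 100 * released_by / length(gg))
  structure(list(
    release_time = ifelse(is.na(release_frame), NA_real_,
                          traj$times[pmin(release_frame + persistence - 1L, nf)]),
    series = series,
    final_pct = series$release_pct[nf],
    n_guests = length(gg)
  ), class = "release_report")
}

#' @export
print.release_report <- function(x, ...) {
  cat(sprintf("<release_report> %d guests; %.1f%% released (%d censored)\n",
              x$n_guests, x$final_pct, sum(is.na(x$release_time))))
  invisible(x)
}

#' Mean square displacement and drift velocity of a group COM
#'
#' Time-lag-averaged MSD of the (unwrapped) group center of mass and the
#' drift velocity from a linear fit of COM displacement along the chosen
#' axis.
#'
#' @param traj a `cg_trajectory` (>= 2 frames).
#' @param group group name or index vector.
#' @param axes columns of the COM used for the MSD (default xy-plane
#'   `c(1, 2)`).
#' @param drift_axis axis for the drift-velocity fit (default 1 = x).
#' @param max_lag_frac largest lag as a fraction of the trajectory length
#'   (default 0.5).
#' @return list with `msd` (data.frame lag ps, msd nm^2) and
#'   `drift_velocity` (nm/ps).
#' @export
msd_and_velocity <- function(traj, group, axes = c(1, 2), drift_axis = 1,
                             max_lag_frac = 0.5) {
  ct <- com_trace(traj, group)
  nf <- nrow(ct)
  if (nf < 2) stop("need at least 2 frames")
  xyz <- as.matrix(ct[, c("x", "y", "z")])
  max_lag <- max(1L, floor((nf - 1) * max_lag_frac))
  msd <- vapply(seq_len(max_lag), function(lag) {
    d <- xyz[seq.int(1 + lag, nf), axes, drop = FALSE] -
      xyz[seq.int(1, nf - lag), axes, drop = FALSE]
    mean(rowSums(d * d))
  }, numeric(1))
  dt <- ct$time[2] - ct$time[1]
  fit <- stats::lm(xyz[, drift_axis] ~ ct$time)
  list(msd = data.frame(lag = seq_len(max_lag) * dt, msd = msd),
       drift_velocity = unname(stats::coef(fit)[2]))
}

#' Per-region occupancy of a COM trace
#'
#' Assigns each frame's group COM (x, y, wrapped into the box) to the
#' surface region containing it; fractions sum to 1.
#'
#' @param traj a `cg_trajectory`.
#' @param spec a `surface_spec`.
#' @param group group name (default `"np_beads"`).
#' @return data.frame with per-region `rho` and occupancy `fraction`.
#' @export
region_occupancy <- function(traj, spec, group = "np_beads") {
  ct <- com_trace(traj, group)
  x <- ct$x %% spec$lx
  y <- ct$y %% spec$ly
  rg <- spec$regions
  counts <- integer(nrow(rg))
  for (r in seq_len(nrow(rg))) {
    counts[r] <- sum(x >= rg$x0[r] & x < rg$x1[r] &
                     y >= rg$y0[r] & y < rg$y1[r])
  }
  data.frame(region = seq_len(nrow(rg)), rho = rg$rho,
             fraction = counts / nrow(ct))
}
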