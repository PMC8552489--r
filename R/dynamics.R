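# Leapfrog stochastic (Langevin) dynamics with frozen beads, COM pulling,
# one-sided z-restraint and trajectory reporters.

#' Integrator parameters
#'
#' Leapfrog Langevin (stochastic dynamics) settings. The default time step
#' is 20 fs (0.02 ps) at 300 K.
#'
#' @param dt time step, ps (default 0.02).
#' @param temperature thermostat temperature, K (default 300).
#' @param gamma friction, ps^-1 per bead (default 1.0, typical for
#'   implicit-solvent CG models).
#' @param seed integer RNG seed for the thermal noise.
#' @param noise logical; FALSE disables the stochastic term (test mode:
#'   with `gamma` ~ 0 the integrator reduces to plain leapfrog).
#' @return an `integrator_params` list.
#' @export
integrator_params <- function(dt = 0.02, temperature = 300, gamma = 1.0,
                              seed = 1, noise = TRUE) {
  stopifnot(dt > 0, temperature > 0, gamma >= 0)
  structure(list(dt = dt, temperature = temperature, gamma = gamma,
                 seed = as.integer(seed), noise = noise),
            class = "integrator_params")
}

new_trajectory <- function(res, system, params, extra = list()) {
  nf <- length(res$frame_times)
  traj <- structure(list(
    times = res$frame_times,
    frames = res$frames,
    energies = as.data.frame(res$energies),
    final_system = within_system(system, res),
    stopped = res$stopped,
    unstable = res$unstable,
    stop_step = res$stop_step,
    metadata = c(list(seed = params$seed, dt = params$dt,
                      temperature = params$temperature,
                      gamma = params$gamma), extra)
  ), class = "cg_trajectory")
  traj
}

within_system <- function(system, res) {
  system$pos <- res$pos
  system$vel <- res$vel
  system$time <- res$final_time
  system
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory>", length(x$times), "frames;",
      sprintf("t = %.2f .. %.2f ps", x$times[1], x$times[length(x$times)]))
  if (isTRUE(x$stopped)) cat(" [stopped at step", x$stop_step, "]")
  if (isTRUE(x$unstable)) cat(" [UNSTABLE]")
  cat("\n")
  invisible(x)
}

#' Steepest-descent energy minimization
#'
#' Damped minimization with backtracking (displacements capped per step),
#' used to remove residual close contacts before production dynamics.
#' Frozen beads never move; the result is deterministic.
#'
#' @inheritParams run_md
#' @param max_steps iteration cap (default 200).
#' @param fmax_tol stop when the largest force component falls below this,
#'   kJ mol^-1 nm^-1 (default 100).
#' @param step0 initial displacement cap, nm.
#' @return the minimized `cg_system`.
#' @export
minimize_system <- function(system, pt, wall = NULL, restraint = NULL,
                            external = NULL, double_well = NULL,
                            max_steps = 200, fmax_tol = 100, step0 = 0.005) {
  ff <- build_ff_list(system, pt, wall, restraint, external, double_well)
  system$pos <- minimize_cpp(unclass(system), ff,
                             max_steps = as.integer(max_steps),
                             fmax_tol = fmax_tol, step0 = step0)
  system
}

#' Run Langevin molecular dynamics
#'
#' Integrates the system with the leapfrog stochastic dynamics integrator:
#' frozen beads never move, thermal noise drives mobile beads to the
#' thermostat temperature, and identical (seed, config) reruns give
#' bit-identical trajectories. Reporters (frames, energies) fire at fixed
#' strides.
#'
#' @param system a `cg_system`.
#' @param n_steps number of steps (0 gives a single-frame trajectory equal
#'   to the input).
#' @param params an [integrator_params()].
#' @param pt a `pair_table`.
#' @param wall,restraint,external,double_well optional force-field terms,
#'   see [total_energy_forces()].
#' @param frame_stride,log_stride reporter strides in steps.
#' @return a `cg_trajectory`: frame times (ps), frame positions, per-frame
#'   energy breakdown plus kinetic temperature, and the final system. A
#'   step moving any bead farther than half the cutoff marks the run
#'   unstable and the last good frame is kept.
#' @export
run_md <- function(system, n_steps, params = integrator_params(), pt,
                   wall = NULL, restraint = NULL, external = NULL,
                   double_well = NULL,
                   frame_stride = max(1L, n_steps %/% 200L),
                   log_stride = max(1L, n_steps %/% 500L)) {
  ff <- build_ff_list(system, pt, wall, restraint, external, double_well)
  integ <- list(dt = params$dt, temperature = params$temperature,
                gamma = params$gamma, seed = params$seed,
                noise = params$noise)
  out <- list(frame_stride = as.integer(frame_stride),
              log_stride = as.integer(log_stride))
  res <- run_engine_cpp(unclass(system), ff, integ, as.integer(n_steps),
                        out, metad = NULL, t0 = system$time)
  if (res$unstable) {
    warning("instability: displacement exceeded rc/2 at step ", res$stop_step,
            "; last good frame persisted")
  }
  new_trajectory(res, system, params)
}

#' Single Langevin step
#'
#' @inheritParams run_md
#' @return the advanced `cg_system`.
#' @export
langevin_step <- function(system, params = integrator_params(), pt,
                          wall = NULL, restraint = NULL, external = NULL,
                          double_well = NULL) {
  run_md(system, 1L, params, pt, wall = wall, restraint = restraint,
         external = external, double_well = double_well,
         frame_stride = 1L, log_stride = 1L)$final_system
}

#' Kinetic temperature of a trajectory
#'
#' @param traj a `cg_trajectory`.
#' @param discard_frac fraction of initial log rows discarded as
#'   equilibration (default 0.2).
#' @return mean kinetic temperature, K.
#' @export
kinetic_temperature <- function(traj, discard_frac = 0.2) {
  tt <- traj$energies$temperature
  mean(tt[seq.int(floor(length(tt) * discard_frac) + 1, length(tt))])
}

#' Extract the COM trace of a group from a trajectory
#'
#' @param traj a `cg_trajectory`.
#' @param group group name or index vector (resolved against the
#'   trajectory's final system).
#' @return data.frame with time and COM x, y, z (nm; positions are
#'   integrated unwrapped, so the trace is continuous across the periodic
#'   boundaries).
#' @export
com_trace <- function(traj, group) {
  g <- get_group(traj$final_system, group)
  m <- traj$final_system$mass[g]
  M <- sum(m)
  com <- t(vapply(traj$frames, function(p) {
    colSums(p[g, , drop = FALSE] * m) / M
  }, numeric(3)))
  data.frame(time = traj$times, x = com[, 1], y = com[, 2], z = com[, 3])
}
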