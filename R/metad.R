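# Metadynamics (standard, well-tempered, multiple-walker, infrequent) on
# COM and contacts collective variables, plus the acceleration-factor
# estimator of unbiased transition times and the Poissonian
# characteristic-time fit.

#' Collective variable specification
#'
#' @param kind `"com_xy"` (NP center-of-mass x and y), `"com_x"` (x only;
#'   1D toys) or `"contacts"` (switched contact count between two groups).
#' @param group bead-group name (COM group, or contacts group A).
#' @param group_b contacts group B (required for `"contacts"`).
#' @param r0 contacts switching radius, nm (default 0.6). The switching
#'   function is the rational form 1/(1 + (r/r0)^6), which equals 1/2 at
#'   r = r0 and is differentiable everywhere (bias forces need dV/ds).
#' @return a `cv_spec` list.
#' @export
cv_spec <- function(kind = c("com_xy", "com_x", "contacts"), group,
                    group_b = NULL, r0 = 0.6) {
  kind <- match.arg(kind)
  if (kind == "contacts") {
    if (is.null(group_b)) stop("contacts CV needs group_b")
    stopifnot(r0 > 0)
  }
  structure(list(kind = kind, group = group, group_b = group_b, r0 = r0),
            class = "cv_spec")
}

#' COM x/y collective variable value
#'
#' Mass-weighted center of mass of a group, x and y components. Positions
#' are integrated unwrapped, so the value is continuous across periodic
#' boundaries.
#'
#' @param system a `cg_system`.
#' @param group group name or index vector.
#' @return length-2 numeric (x, y), nm.
#' @export
cv_com_xy <- function(system, group) {
  center_of_mass(system, group)[1:2]
}

#' Switched contacts collective variable value
#'
#' Sum over A-B bead pairs of the rational switching function
#' 1/(1 + (r/r0)^6): a differentiable contact count bounded by |A| x |B|.
#'
#' @param system a `cg_system`.
#' @param group_a,group_b group names or index vectors (disjoint).
#' @param r0 switching radius, nm.
#' @return scalar contact count.
#' @export
cv_contacts <- function(system, group_a, group_b, r0 = 0.6) {
  ga <- get_group(system, group_a)
  gb <- get_group(system, group_b)
  if (length(intersect(ga, gb))) stop("contacts groups must be disjoint")
  switched_contacts_cpp(system$pos[ga, , drop = FALSE],
                        system$pos[gb, , drop = FALSE], r0)[1]
}

#' Metadynamics configuration
#'
#' Gaussian kernel deposition schedule. With `bias_factor` set the bias is
#' well-tempered: each kernel's effective height is damped by
#' exp(-V(s)/(kB T (gamma_b - 1))).
#'
#' @param height kernel height h, kJ/mol.
#' @param width kernel width per CV dimension (nm for COM CVs, contact
#'   units for the contacts CV); recycled.
#' @param stride deposition stride, steps.
#' @param bias_factor well-tempered bias factor gamma_b > 1, or NULL for
#'   standard metadynamics.
#' @param cv_stride CV/bias logging stride, steps (default 10).
#' @param grid_min,grid_max,grid_bins optional bias-grid bounds and size
#'   per CV dimension (COM CVs are grid-backed; defaults cover the box,
#'   periodic in x/y).
#' @param stop optional stop condition `list(op = "lt"|"gt", value,
#'   persistence, check_stride)` on the (scalar) CV: the run terminates
#'   once the condition has held for `persistence` consecutive checks.
#' @return a `metad_config` list.
#' @export
metad_config <- function(height, width, stride, bias_factor = NULL,
                         cv_stride = 10L, grid_min = NULL, grid_max = NULL,
                         grid_bins = NULL, stop = NULL) {
  stopifnot(height >= 0, all(width > 0), stride >= 1)
  if (!is.null(bias_factor)) stopifnot(bias_factor > 1)
  if (!is.null(stop)) {
    stopifnot(stop$op %in% c("lt", "gt"))
    stop <- list(op = stop$op, value = stop$value,
                 persistence = as.integer(stop$persistence %||% 1L),
                 check_stride = as.integer(stop$check_stride %||% 10L))
  }
  structure(list(height = height, width = width, stride = as.integer(stride),
                 bias_factor = bias_factor, cv_stride = as.integer(cv_stride),
                 grid_min = grid_min, grid_max = grid_max,
                 grid_bins = grid_bins, stop = stop),
            class = "metad_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# assemble the metad list handed to the C++ engine
build_metad_list <- function(system, cv, cfg, kernels = NULL) {
  ndim <- if (cv$kind == "com_xy") 2L else 1L
  m <- list(cv_kind = cv$kind,
            group = get_group(system, cv$group),
            height = cfg$height,
            width = rep_len(cfg$width, ndim),
            stride = cfg$stride,
            bias_factor = cfg$bias_factor,
            cv_stride = cfg$cv_stride,
            stop = cfg$stop,
            kernels = kernels)
  if (cv$kind == "contacts") {
    m$group_b <- get_group(system, cv$group_b)
    m$r0 <- cv$r0
    m$grid_mode <- FALSE
  } else {
    m$grid_mode <- TRUE
    w <- rep_len(cfg$width, ndim)
    if (cv$kind == "com_xy") {
      gmin <- cfg$grid_min %||% c(0, 0)
      gmax <- cfg$grid_max %||% system$box[1:2]
      gper <- system$periodic[1:2]
    } else {
      gmin <- cfg$grid_min %||% 0
      gmax <- cfg$grid_max %||% system$box[1]
      gper <- system$periodic[1]
    }
    bins <- cfg$grid_bins %||% pmax(50L, ceiling((gmax - gmin) / (w / 2)))
    m$grid_min <- gmin
    m$grid_max <- gmax
    m$grid_bins <- as.integer(bins)
    m$grid_periodic <- gper
  }
  m
}

new_bias <- function(res, cv, cfg, m, temperature) {
  ndim <- if (cv$kind == "com_xy") 2L else 1L
  k <- res$kernels
  colnames(k) <- c(paste0("center", seq_len(ndim)), "height", "time")
  b <- list(cv_kind = cv$kind, kernels = k,
            width = rep_len(cfg$width, ndim),
            bias_factor = cfg$bias_factor, temperature = temperature)
  if (!is.null(res$bias_grid)) {
    b$grid <- list(V = res$bias_grid, dim = res$grid_dim,
                   min = m$grid_min, max = m$grid_max,
                   periodic = m$grid_periodic)
  }
  structure(b, class = "cg_bias")
}

#' @export
print.cg_bias <- function(x, ...) {
  cat("<cg_bias>", x$cv_kind, "|", nrow(x$kernels), "kernels |",
      if (is.null(x$bias_factor)) "standard" else
        paste0("well-tempered (gamma_b = ", x$bias_factor, ")"), "\n")
  invisible(x)
}

#' Evaluate the deposited bias at CV points
#'
#' V(s) as the sum of all deposited (already damped) Gaussian kernels.
#'
#' @param bias a `cg_bias`.
#' @param s numeric vector (1D CV) or 2-column matrix (2D CV) of CV
#'   points.
#' @return bias values, kJ/mol.
#' @export
bias_value <- function(bias, s) {
  k <- bias$kernels
  ndim <- length(bias$width)
  s <- if (ndim == 1) matrix(as.numeric(s), ncol = 1) else as.matrix(s)
  if (nrow(k) == 0) return(numeric(nrow(s)))
  e <- 0
  for (d in seq_len(ndim)) {
    u <- outer(s[, d], k[, d], "-")
    e <- e + u^2 / (2 * bias$width[d]^2)
  }
  as.numeric(exp(-e) %*% k[, ndim + 1])
}

#' Deposit a metadynamics kernel
#'
#' Appends one Gaussian kernel at the current CV point. With a bias factor
#' set, the effective height is damped well-tempered style:
#' h_eff = h exp(-V(s)/(kB T (gamma_b - 1))); the first deposit therefore
#' has height exactly h, and with standard metadynamics n deposits at one
#' point give V = n h there.
#'
#' @param bias a `cg_bias` (or NULL to start an empty bias).
#' @param s CV point (numeric, length = CV dimension).
#' @param cfg a [metad_config()].
#' @param temperature K.
#' @param time deposit time, ps.
#' @param cv_kind CV kind when starting a fresh bias.
#' @return the updated `cg_bias`.
#' @export
metad_deposit <- function(bias, s, cfg, temperature = 300, time = 0,
                          cv_kind = "com_x") {
  ndim <- length(s)
  if (is.null(bias)) {
    k <- matrix(numeric(0), 0, ndim + 2)
    bias <- structure(list(cv_kind = cv_kind, kernels = k,
                           width = rep_len(cfg$width, ndim),
                           bias_factor = cfg$bias_factor,
                           temperature = temperature), class = "cg_bias")
  }
  v_here <- bias_value(bias, matrix(s, ncol = ndim))
  h_eff <- cfg$height
  if (!is.null(cfg$bias_factor)) {
    h_eff <- cfg$height *
      exp(-v_here / (.kB * temperature * (cfg$bias_factor - 1)))
  }
  bias$kernels <- rbind(bias$kernels, c(s, h_eff, time))
  colnames(bias$kernels) <- c(paste0("center", seq_len(ndim)), "height", "time")
  bias
}

#' Run metadynamics
#'
#' Langevin dynamics with Gaussian bias deposition on the chosen CV. The
#' bias force -dV/ds is mapped to bead forces by the CV chain rule; COM
#' CVs bias only the in-plane NP position (never z). COM-CV biases are
#' grid-backed for O(1) evaluation; the contacts CV uses direct kernel
#' summation.
#'
#' @inheritParams run_md
#' @param cv a [cv_spec()].
#' @param cfg a [metad_config()].
#' @param bias optional starting `cg_bias` (restart / shared-bias
#'   walkers): its kernels are replayed at their stored heights.
#' @return list with `trajectory` (`cg_trajectory`), `bias` (`cg_bias`),
#'   `cv_log` (data.frame time, CV components, V) and
#'   `log_mean_expbetaV` (log acceleration factor over the run).
#' @export
run_metad <- function(system, cv, cfg, params = integrator_params(), pt,
                      n_steps, wall = NULL, restraint = NULL,
                      external = NULL, double_well = NULL, bias = NULL,
                      frame_stride = max(1L, n_steps %/% 200L),
                      log_stride = max(1L, n_steps %/% 500L)) {
  ff <- build_ff_list(system, pt, wall, restraint, external, double_well)
  integ <- list(dt = params$dt, temperature = params$temperature,
                gamma = params$gamma, seed = params$seed,
                noise = params$noise)
  out <- list(frame_stride = as.integer(frame_stride),
              log_stride = as.integer(log_stride))
  m <- build_metad_list(system, cv, cfg,
                        kernels = if (!is.null(bias)) unname(bias$kernels))
  res <- run_engine_cpp(unclass(system), ff, integ, as.integer(n_steps),
                        out, metad = m, t0 = system$time)
  ndim <- if (cv$kind == "com_xy") 2L else 1L
  cl <- as.data.frame(res$cv_log)
  names(cl) <- c("time", paste0("s", seq_len(ndim)), "V")
  traj <- new_trajectory(res, system, params,
                         extra = list(metad = TRUE, cv_kind = cv$kind))
  list(trajectory = traj,
       bias = new_bias(res, cv, cfg, m, params$temperature),
       cv_log = cl,
       log_mean_expbetaV = res$log_mean_expbetaV,
       stopped = res$stopped)
}

#' Multiple-walker metadynamics
#'
#' Runs `n_walkers` replicas of the same system that read and deposit into
#' one shared bias. Walkers are synchronized every deposition stride; the
#' kernel merge order (walker 1, 2, ...) is deterministic given the
#' per-walker seeds.
#'
#' @inheritParams run_metad
#' @param n_walkers number of walkers.
#' @param seeds per-walker integer seeds (default `seed + 0:(n-1)`).
#' @param n_steps steps per walker (a multiple of `cfg$stride`; rounded up
#'   if not).
#' @return list with per-walker `trajectories`, per-walker `cv_logs`, and
#'   the shared `bias`.
#' @export
run_multiple_walker <- function(system, cv, cfg, params = integrator_params(),
                                pt, n_steps, n_walkers,
                                seeds = params$seed + seq_len(n_walkers) - 1L,
                                wall = NULL, restraint = NULL,
                                external = NULL, double_well = NULL) {
  stopifnot(n_walkers >= 1, length(seeds) == n_walkers)
  rounds <- ceiling(n_steps / cfg$stride)
  walkers <- replicate(n_walkers, system, simplify = FALSE)
  cv_logs <- vector("list", n_walkers)
  frames <- lapply(seq_len(n_walkers), function(i) list())
  frame_times <- lapply(seq_len(n_walkers), function(i) numeric(0))
  shared <- NULL  # kernel matrix
  cfg1 <- cfg
  last <- NULL
  for (r in seq_len(rounds)) {
    new_kernels <- list()
    for (w in seq_len(n_walkers)) {
      pw <- params
      pw$seed <- as.integer((seeds[w] * 1009L + r) %% .Machine$integer.max)
      res <- run_metad(walkers[[w]], cv, cfg1, pw, pt,
                       n_steps = cfg$stride, wall = wall,
                       restraint = restraint, external = external,
                       double_well = double_well,
                       bias = if (!is.null(shared))
                         structure(list(cv_kind = cv$kind, kernels = shared,
                                        width = rep_len(cfg$width,
                                                        if (cv$kind == "com_xy") 2L else 1L),
                                        bias_factor = cfg$bias_factor,
                                        temperature = params$temperature),
                                   class = "cg_bias"),
                       frame_stride = cfg$stride, log_stride = cfg$stride)
      walkers[[w]] <- res$trajectory$final_system
      nk <- nrow(res$bias$kernels)
      n0 <- if (is.null(shared)) 0 else nrow(shared)
      if (nk > n0) new_kernels[[length(new_kernels) + 1]] <-
          res$bias$kernels[seq.int(n0 + 1, nk), , drop = FALSE]
      cv_logs[[w]] <- rbind(cv_logs[[w]], res$cv_log[-1, , drop = FALSE])
      fr <- res$trajectory
      frames[[w]] <- c(frames[[w]], fr$frames[-1])
      frame_times[[w]] <- c(frame_times[[w]], fr$times[-1])
      last <- res
    }
    for (k in new_kernels) shared <- rbind(shared, unname(k))
  }
  bias <- last$bias
  bias$kernels <- shared
  colnames(bias$kernels) <- colnames(last$bias$kernels)
  trajs <- lapply(seq_len(n_walkers), function(w) {
    structure(list(times = frame_times[[w]], frames = frames[[w]],
                   energies = NULL, final_system = walkers[[w]],
                   stopped = FALSE, unstable = FALSE, stop_step = -1,
                   metadata = list(seed = seeds[w], walker = w)),
              class = "cg_trajectory")
  })
  list(trajectories = trajs, cv_logs = cv_logs, bias = bias)
}

#' Infrequent metadynamics run
#'
#' Sparse well-tempered deposition on a CV with a stop condition; returns
#' the biased time to the transition and the acceleration factor
#' alpha = <exp(beta V(s(t), t))> averaged over the run, giving the
#' unbiased transition time t = alpha x t_MetaD. Runs that exhaust
#' `max_steps` without transitioning are flagged censored.
#'
#' @inheritParams run_metad
#' @param max_steps step budget.
#' @return a `transition_record`: `t_metad` (ps), `alpha`, `log_alpha`,
#'   `t_unbiased` (ps), `censored`, `cv_final`, and the run's `bias`.
#' @export
run_infrequent_metad <- function(system, cv, cfg, params = integrator_params(),
                                 pt, max_steps, wall = NULL,
                                 restraint = NULL, external = NULL,
                                 double_well = NULL) {
  if (is.null(cfg$stop)) stop("infrequent metadynamics needs a stop condition")
  res <- run_metad(system, cv, cfg, params, pt, n_steps = max_steps,
                   wall = wall, restraint = restraint, external = external,
                   double_well = double_well,
                   frame_stride = max_steps, log_stride = max_steps)
  t_metad <- res$trajectory$final_system$time - system$time
  log_alpha <- res$log_mean_expbetaV
  cvf <- res$cv_log[nrow(res$cv_log), ]
  structure(list(t_metad = t_metad,
                 alpha = exp(log_alpha),
                 log_alpha = log_alpha,
                 t_unbiased = exp(log_alpha) * t_metad,
                 censored = !res$stopped,
                 cv_final = as.numeric(cvf[2]),
                 n_kernels = nrow(res$bias$kernels),
                 bias = res$bias),
            class = "transition_record")
}

#' @export
print.transition_record <- function(x, ...) {
  cat(sprintf("<transition_record> t_MetaD = %.3g ps | alpha = %.3g | t = %.3g ps%s\n",
              x$t_metad, x$alpha, x$t_unbiased,
              if (x$censored) " [censored]" else ""))
  invisible(x)
}

#' Unbiased first-passage time
#'
#' Plain Langevin dynamics monitored on a scalar CV with a stop
#' condition; the brute-force oracle against which the infrequent
#' metadynamics estimator is validated.
#'
#' @inheritParams run_metad
#' @param stop stop condition as in [metad_config()].
#' @param max_steps step budget.
#' @return list with `time` (ps; NA if censored), `censored`, and the
#'   final CV value.
#' @export
first_passage_time <- function(system, cv, stop, params = integrator_params(),
                               pt, max_steps, wall = NULL, restraint = NULL,
                               external = NULL, double_well = NULL,
                               width = 0.1) {
  cfg <- metad_config(height = 0, width = width, stride = max_steps + 1L,
                      cv_stride = max_steps, stop = stop,
                      grid_min = if (cv$kind != "contacts") -1e3,
                      grid_max = if (cv$kind != "contacts") 1e3,
                      grid_bins = if (cv$kind != "contacts") 11L)
  res <- run_metad(system, cv, cfg, params, pt, n_steps = max_steps,
                   wall = wall, restraint = restraint, external = external,
                   double_well = double_well,
                   frame_stride = max_steps, log_stride = max_steps)
  t <- res$trajectory$final_system$time - system$time
  list(time = if (res$stopped) t else NA_real_, censored = !res$stopped,
       cv_final = res$cv_log[nrow(res$cv_log), 2])
}

#' Acceleration factor from a bias log
#'
#' alpha = <exp(beta V(s(t), t))> with beta = 1/(kB T), the time average
#' running over the logged frames (log-sum-exp accumulation, overflow
#' safe). With V = 0 everywhere alpha = 1; V >= 0 implies alpha >= 1.
#'
#' @param cv_log data.frame with a `V` column (kJ/mol), or a numeric
#'   vector of V values.
#' @param temperature K.
#' @return the dimensionless acceleration factor.
#' @export
acceleration_factor <- function(cv_log, temperature = 300) {
  v <- if (is.data.frame(cv_log)) cv_log$V else as.numeric(cv_log)
  if (!length(v)) stop("empty bias log")
  b <- v / (.kB * temperature)
  mx <- max(b)
  exp(mx + log(mean(exp(b - mx))))
}

#' Poissonian fit of transition times
#'
#' Fits P(n >= 1)(t) = 1 - exp(-t/tau) to a set of unbiased transition
#' times: tau is the exponential maximum-likelihood estimate (the sample
#' mean), and self-consistency is checked with a two-sided
#' Kolmogorov-Smirnov test against Exp(tau).
#'
#' @param times positive transition times (censored runs excluded by the
#'   caller; a single time gives the point estimate only).
#' @return a `poisson_fit`: `tau`, `ks_stat`, `p_value`, `n`, `method`.
#' @export
fit_poisson_tau <- function(times) {
  times <- as.numeric(times)
  if (!length(times)) stop("no uncensored transition times: no estimate")
  if (any(times < 0)) stop("transition times must be >= 0")
  tau <- mean(times)
  if (length(times) >= 2 && tau > 0) {
    ks <- suppressWarnings(stats::ks.test(times, stats::pexp, rate = 1 / tau))
    stat <- unname(ks$statistic)
    pv <- ks$p.value
  } else {
    stat <- NA_real_
    pv <- NA_real_
  }
  structure(list(tau = tau, ks_stat = stat, p_value = pv,
                 n = length(times), method = "exponential MLE (sample mean)"),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("<poisson_fit> tau = %.4g ps (n = %d); KS D = %.3f, p = %.3f\n",
              x$tau, x$n, x$ks_stat, x$p_value))
  invisible(x)
}

#' Free-energy estimate from a well-tempered bias
#'
#' For a converged well-tempered bias, F(s) = -V(s)/(1 - 1/gamma_b) up to
#' an additive constant (standard metadynamics: F = -V). Returned shifted
#' so min F = 0.
#'
#' @param bias a `cg_bias` with a 1D grid.
#' @return data.frame with CV grid `s` and free energy `F` (kJ/mol).
#' @export
metad_free_energy <- function(bias) {
  if (is.null(bias$grid)) stop("free-energy estimate needs a grid-backed bias")
  g <- bias$grid
  if (g$dim[2] != 1) stop("only 1D grids supported here")
  n <- g$dim[1]
  s <- seq(g$min, g$max, length.out = if (g$periodic) n + 1 else n)[seq_len(n)]
  fac <- if (is.null(bias$bias_factor)) 1 else (1 - 1 / bias$bias_factor)
  f <- -g$V / fac
  data.frame(s = s, F = f - min(f))
}
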