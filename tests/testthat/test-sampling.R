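# Collective variables, metadynamics deposition, walkers, infrequent
# metadynamics bookkeeping and the Poissonian characteristic-time fit.

test_that("COM CV is the mass-weighted center and stays continuous across wraps", {
  s <- cg_system(rbind(c(1, 2, 3)), "M", box = c(10, 10, 10))
  s$groups <- list(g = 1L)
  expect_equal(unname(cv_com_xy(s, "g")), c(1, 2))
  s2 <- cg_system(rbind(c(0, 0, 0), c(2, 0, 0)), c("M", "M"),
                  box = c(10, 10, 10))
  s2$groups <- list(g = 1:2)
  expect_equal(unname(cv_com_xy(s2, "g")), c(1, 0))
  # a pair straddling x = 0: integrated positions are unwrapped, so the CV
  # never jumps by lx as beads cross the boundary
  s3 <- cg_system(rbind(c(-0.4, 1, 1), c(0.4, 1, 1)), c("M", "M"),
                  box = c(10, 10, 10))
  s3$groups <- list(g = 1:2)
  expect_equal(unname(cv_com_xy(s3, "g")), c(0, 1))
})

test_that("switched contacts take the 1/2 value at r0 and respect the bound", {
  mk <- function(r) {
    s <- cg_system(rbind(c(0, 0, 0), c(r, 0, 0)), c("M", "R"),
                   box = c(20, 20, 20))
    s$groups <- list(a = 1L, b = 2L)
    s
  }
  expect_equal(cv_contacts(mk(0.6), "a", "b", r0 = 0.6), 0.5)
  expect_lt(cv_contacts(mk(5), "a", "b", r0 = 0.6), 1e-5)
  set.seed(1)
  s <- cg_system(matrix(runif(60, 0, 2), 20, 3),
                 rep(c("M", "R"), 10), box = c(20, 20, 20))
  s$groups <- list(a = which(s$type == 1), b = which(s$type == 3))
  val <- cv_contacts(s, "a", "b", r0 = 0.6)
  expect_lte(val, length(s$groups$a) * length(s$groups$b))
  expect_gte(val, 0)
})

test_that("kernel deposition: first height exact, standard MetaD superposes, well-tempered damps", {
  cfg <- metad_config(height = 2, width = 0.3, stride = 10)
  b <- metad_deposit(NULL, 0.5, cfg, time = 0)
  expect_equal(unname(b$kernels[1, "height"]), 2)
  for (i in 1:4) b <- metad_deposit(b, 0.5, cfg, time = i)
  expect_equal(bias_value(b, 0.5), 5 * 2)  # n deposits at one point -> n h
  # well-tempered heights are non-increasing at a revisited point
  cfgw <- metad_config(height = 2, width = 0.3, stride = 10, bias_factor = 5)
  bw <- NULL
  for (i in 1:6) bw <- metad_deposit(bw, 0.5, cfgw, time = i)
  h <- bw$kernels[, "height"]
  expect_equal(h[1], 2)
  expect_true(all(diff(h) < 0))
  expect_true(all(h > 0))
})

test_that("zero-height kernels reproduce the unbiased trajectory bit for bit", {
  sys <- toy_1d_system()
  cfg <- metad_config(height = 0, width = 0.15, stride = 100,
                      grid_min = -3, grid_max = 3, grid_bins = 101)
  cv <- cv_spec("com_x", "bead")
  a <- run_metad(sys, cv, cfg, integrator_params(seed = 9),
                 free_pair_table(), n_steps = 2000, double_well = double_well)
  b <- run_md(sys, 2000, integrator_params(seed = 9), free_pair_table(),
              double_well = double_well)
  expect_identical(a$trajectory$final_system$pos, b$final_system$pos)
  expect_equal(acceleration_factor(a$cv_log), 1)
})

test_that("metadynamics escapes a double well that unbiased dynamics cannot", {
  sys <- toy_1d_system(-1)
  cv <- cv_spec("com_x", "bead")
  steps <- 3e4
  un <- run_md(sys, steps, integrator_params(seed = 21), free_pair_table(),
               double_well = double_well, frame_stride = 50)
  xu <- vapply(un$frames, function(p) p[1, 1], numeric(1))
  expect_true(all(xu < 0))  # stuck in the starting well at this length
  cfg <- metad_config(height = 1.2, width = 0.15, stride = 250,
                      grid_min = -3, grid_max = 3, grid_bins = 241)
  me <- run_metad(sys, cv, cfg, integrator_params(seed = 21),
                  free_pair_table(), n_steps = steps,
                  double_well = double_well, frame_stride = 50)
  xm <- vapply(me$trajectory$frames, function(p) p[1, 1], numeric(1))
  expect_true(any(xm > 0.5) && any(xm < -0.5))  # both wells visited
})

test_that("well-tempered bias recovers the analytic double-well free energy", {
  sys <- toy_1d_system()
  cv <- cv_spec("com_x", "bead")
  cfg <- metad_config(height = 1.2, width = 0.15, stride = 500,
                      bias_factor = 5, grid_min = -2.5, grid_max = 2.5,
                      grid_bins = 401)
  res <- run_metad(sys, cv, cfg, integrator_params(seed = 5),
                   free_pair_table(), n_steps = 1.5e6,
                   double_well = double_well)
  fe <- metad_free_energy(res$bias)
  sel <- abs(fe$s) <= 1.2
  ref <- double_well$barrier * ((fe$s / double_well$half_sep)^2 - 1)^2
  err <- (fe$F - ref)
  err <- err - mean(err[sel])  # free energies match up to a constant
  expect_lt(max(abs(err[sel])), 0.5 * kB() * 300)
})

test_that("multiple walkers share one bias with deterministic bookkeeping", {
  sys <- toy_1d_system()
  cv <- cv_spec("com_x", "bead")
  cfg <- metad_config(height = 1.0, width = 0.15, stride = 200,
                      grid_min = -3, grid_max = 3, grid_bins = 241)
  mw <- run_multiple_walker(sys, cv, cfg, integrator_params(seed = 3),
                            free_pair_table(), n_steps = 2000, n_walkers = 4,
                            double_well = double_well)
  expect_equal(nrow(mw$bias$kernels), 4 * (2000 / 200))
  mw2 <- run_multiple_walker(sys, cv, cfg, integrator_params(seed = 3),
                             free_pair_table(), n_steps = 2000, n_walkers = 4,
                             double_well = double_well)
  expect_identical(mw$bias$kernels, mw2$bias$kernels)
  # single walker reduces to plain metadynamics kernel-for-kernel
  one <- run_multiple_walker(sys, cv, cfg, integrator_params(seed = 3),
                             free_pair_table(), n_steps = 1000, n_walkers = 1)
  expect_equal(nrow(one$bias$kernels), 5)
})

test_that("acceleration factor: closed forms and invariants", {
  kT <- kB() * 300
  expect_equal(acceleration_factor(rep(0, 100)), 1)
  expect_equal(acceleration_factor(rep(kT * log(10), 50)), 10,
               tolerance = 1e-12)
  expect_equal(acceleration_factor(rep(2.494 * log(10), 50)), 10,
               tolerance = 2e-3)  # kB T = 2.494 kJ/mol at 300 K
  # V >= 0 implies alpha >= 1 (Jensen) for any log
  set.seed(2)
  expect_gte(acceleration_factor(runif(100, 0, 30)), 1)
  # overflow-safe for large biases
  expect_true(is.finite(log(acceleration_factor(seq(0, 500, by = 10)))))
})

test_that("a stop condition already true at t = 0 yields a zero-time record", {
  sys <- toy_1d_system(2)  # beyond the x > 0.9 stop already
  cv <- cv_spec("com_x", "bead")
  cfg <- metad_config(height = 1.2, width = 0.15, stride = 1e5,
                      bias_factor = 10, grid_min = -3, grid_max = 3,
                      grid_bins = 101,
                      stop = list(op = "gt", value = 0.9, persistence = 1,
                                  check_stride = 1))
  rec <- run_infrequent_metad(sys, cv, cfg, integrator_params(seed = 1),
                              free_pair_table(), max_steps = 1000,
                              double_well = double_well)
  expect_false(rec$censored)
  expect_lt(rec$t_metad, 0.05)  # terminates at the first check
  expect_equal(rec$alpha, 1, tolerance = 1e-10)
})

test_that("a run exhausting its budget is flagged censored", {
  sys <- toy_1d_system(-1)
  cv <- cv_spec("com_x", "bead")
  cfg <- metad_config(height = 0.1, width = 0.15, stride = 1e5,
                      grid_min = -3, grid_max = 3, grid_bins = 101,
                      stop = list(op = "gt", value = 0.9, persistence = 1,
                                  check_stride = 10))
  rec <- run_infrequent_metad(sys, cv, cfg, integrator_params(seed = 2),
                              free_pair_table(), max_steps = 2000,
                              double_well = double_well)
  expect_true(rec$censored)
})

test_that("Poisson fit: MLE, scale equivariance and self-consistency", {
  expect_equal(fit_poisson_tau(3.7)$tau, 3.7)  # single time -> point MLE
  set.seed(4)
  x <- stats::rexp(1000, rate = 1 / 2)
  fit <- fit_poisson_tau(x)
  expect_true(fit$tau > 1.9 && fit$tau < 2.1)
  expect_gt(fit$p_value, 0.05)
  # scale equivariance
  fit10 <- fit_poisson_tau(10 * x)
  expect_equal(fit10$tau, 10 * fit$tau)
  expect_equal(fit10$ks_stat, fit$ks_stat)
  set.seed(8)
  small <- stats::rexp(30)
  expect_gt(fit_poisson_tau(small)$p_value, 0.05)
  expect_error(fit_poisson_tau(numeric(0)), "no uncensored")
})

test_that("unbiased time is never shorter than biased time (V >= 0)", {
  sys <- toy_1d_system(-1)
  cv <- cv_spec("com_x", "bead")
  cfg <- metad_config(height = 1.2, width = 0.15, stride = 500,
                      bias_factor = 10, grid_min = -2.5, grid_max = 2.5,
                      grid_bins = 201,
                      stop = list(op = "gt", value = 0.9, persistence = 1,
                                  check_stride = 20))
  for (s in 1:3) {
    rec <- run_infrequent_metad(sys, cv, cfg, integrator_params(seed = 30 + s),
                                free_pair_table(), max_steps = 2e5,
                                double_well = double_well)
    expect_gte(rec$alpha, 1)
    expect_gte(rec$t_unbiased, rec$t_metad)
  }
})
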