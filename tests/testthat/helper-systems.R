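# small fixture builders used across tests

free_pair_table <- function() pair_table("M", sigma0 = 0.47, eps0 = 0)

toy_1d_system <- function(x0 = -1) {
  s <- cg_system(matrix(c(x0, 0, 5), 1, 3), "M", box = c(10, 10, 10),
                 periodic = c(FALSE, FALSE, FALSE))
  s$groups <- list(bead = 1L)
  s
}

double_well <- list(barrier = 10, half_sep = 1)  # ~4 kBT at 300 K

# minimum-image pair distances (periodic in x and y)
min_image_dist <- function(pos, box) {
  n <- nrow(pos)
  d <- matrix(10, n, n)
  for (i in seq_len(n - 1)) {
    dx <- sweep(pos[seq.int(i + 1, n), , drop = FALSE], 2, pos[i, ])
    for (k in 1:2) dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
    d[i, seq.int(i + 1, n)] <- sqrt(rowSums(dx^2))
  }
  pmin(d, t(d))
}

random_mixed_system <- function(n = 50, seed = 42, box = c(8, 8, 8)) {
  set.seed(seed)
  # rejection-sample so no pair overlaps hard or sits within 0.05 nm of the
  # 1.1 nm cutoff (finite differences across the truncation radius are
  # meaningless)
  repeat {
    pos <- matrix(runif(3 * n, 0.3, box[1] - 0.3), n, 3)
    pos[, 3] <- 0.5 + (pos[, 3] - 0.3) * (box[3] - 1.0) / (box[1] - 0.6)
    d <- min_image_dist(pos, box)
    if (min(d) > 0.25 && !any(abs(d - 1.1) < 0.05)) break
  }
  cg_system(pos, rep(c("M", "G"), length.out = n), box = box)
}

# quasi-uniform unit directions (golden-angle spiral)
fibonacci_dirs <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

# central finite-difference forces from total_energy_forces
fd_forces <- function(sys, pt, h = 1e-6, ...) {
  n <- n_beads(sys)
  fd <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (k in 1:3) {
      sp <- sys; sp$pos[i, k] <- sp$pos[i, k] + h
      sm <- sys; sm$pos[i, k] <- sm$pos[i, k] - h
      fd[i, k] <- -(total_energy_forces(sp, pt, ...)$energy$total -
                    total_energy_forces(sm, pt, ...)$energy$total) / (2 * h)
    }
  }
  fd
}
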