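p_ap <- sim_params(use_cells = FALSE)

test_that("the pair potential scales its well linearly and vanishes at rc", {
  r <- seq(0.06, 1.5, length.out = 600)

  ## factor 0: purely repulsive, no well
  e0 <- pair_potential(r, 0)$energy
  expect_gte(min(e0), 0)

  ## doubling the factor doubles the well depth exactly
  e1 <- pair_potential(r, 1)$energy
  e2 <- pair_potential(r, 2)$energy
  expect_equal(min(e2), 2 * min(e1), tolerance = 1e-12)
  ## well depth exactly factor * eps_att at the WCA minimum
  rmin <- 2^(1 / 6) * sim_params()$sigma
  expect_equal(pair_potential(rmin, 1)$energy, -sim_params()$eps_att)
  expect_equal(pair_potential(rmin, 2)$energy, -2 * sim_params()$eps_att)

  ## zero at the cutoff
  expect_equal(pair_potential(1.5, 1)$energy, 0, tolerance = 1e-12)
  expect_error(pair_potential(0, 1), "r <= 0")
  expect_error(pair_potential(1, -0.5), "negative")
})

test_that("tabulated potentials match the closed form and -dE/dr", {
  tab <- build_interaction_table()
  pots <- tabulate_potentials(tab, n = 2000L)
  tt <- pots[["PL_tail|PL_tail"]]
  ## table values equal direct evaluation
  direct <- pair_potential(tt$r, tab["PL_tail", "PL_tail"])
  expect_equal(tt$energy, direct$energy, tolerance = 1e-12)
  ## force consistent with central differences of the energy on interior
  ## points (away from the core where E varies over orders of magnitude)
  i <- which(tt$r > 0.55 & tt$r < 1.45)
  i <- i[i > 1 & i < nrow(tt)]
  fd <- -(tt$energy[i + 1L] - tt$energy[i - 1L]) / (tt$r[i + 1L] - tt$r[i - 1L])
  scale <- max(abs(tt$force[i]))
  expect_lt(max(abs(fd - tt$force[i])) / scale, 1e-3)
})

test_that("analytic forces match central finite differences of the energy", {
  sys <- lattice_system()
  f <- compute_forces(sys, params = p_ap)
  h <- 1e-6
  err <- 0
  for (i in seq_len(n_beads(sys))) for (d in 1:3) {
    up <- sys; up$x[i, d] <- up$x[i, d] + h
    dn <- sys; dn$x[i, d] <- dn$x[i, d] - h
    fd <- -(compute_forces(up, params = p_ap)$epot -
            compute_forces(dn, params = p_ap)$epot) / (2 * h)
    err <- max(err, abs(fd - f$forces[i, d]) / max(1, abs(f$forces[i, d])))
  }
  expect_lt(err, 1e-6)
})

test_that("forces respect Newton's third law and basic mechanics", {
  sys <- lattice_system()
  f <- compute_forces(sys, params = p_ap)
  ## total force vanishes (translational invariance; periodic pairs cancel)
  expect_lt(max(abs(colSums(f$forces))), 1e-7)

  ## a bonded pair at its rest length feels no bond force
  x <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  sys2 <- cg_system(x, c("PL_head", "PL_head"), c(1L, 1L),
                    bonds = data.frame(i = 1L, j = 2L, k = 2.5, r0 = 0.5),
                    box = c(10, 10, 10))
  f2 <- compute_forces(sys2, params = p_ap)
  expect_lt(max(abs(f2$forces)), 1e-10)
  expect_equal(f2$epot, 0)

  ## overlapping beads below the table range are detected
  x3 <- rbind(c(0, 0, 0), c(0.01, 0, 0))
  sys3 <- cg_system(x3, c("PL_tail", "PL_tail"), c(1L, 2L),
                    box = c(10, 10, 10))
  expect_error(compute_forces(sys3, params = p_ap), "overlap")
})

test_that("cell-list and all-pairs neighbour searches agree", {
  sys <- gen_bilayer_patch(120, n_tg = 4, mode = "lens", seed = 6L)
  f_cells <- compute_forces(sys, params = sim_params(use_cells = TRUE))
  f_all <- compute_forces(sys, params = sim_params(use_cells = FALSE))
  expect_equal(f_cells$epot, f_all$epot, tolerance = 1e-12)
  expect_equal(f_cells$forces, f_all$forces, tolerance = 1e-10)
})

test_that("without friction the integrator conserves energy", {
  set.seed(9)
  n <- 100L
  g <- expand.grid(x = 1:5, y = 1:5, z = 1:4)
  x <- as.matrix(g) + matrix(runif(3 * n, -0.05, 0.05), n, 3)
  sys <- cg_system(x, rep("PL_tail", n), seq_len(n), box = c(10, 10, 10))
  eq <- run_cg(sys, sim_params(dt = 20, damping = 2000, seed = 3L),
               n_steps = 2000L, stride = 2000L)
  nve <- run_cg(eq$system, sim_params(dt = 5, damping = Inf),
                n_steps = 10000L, stride = 10L, v0 = eq$v)
  E <- nve$log$epot + nve$log$ekin
  expect_lt(max(abs(E - E[1L])) / abs(E[1L]), 1e-4)
})

test_that("the Langevin thermostat holds the target temperature", {
  n <- 200L
  g <- expand.grid(x = 1:6, y = 1:6, z = 1:6)[seq_len(n), ]
  sys <- cg_system(as.matrix(g) * 1.1, rep("PL_tail", n), seq_len(n),
                   box = c(12, 12, 12))
  r <- run_cg(sys, sim_params(dt = 50, damping = 1e4, seed = 11L),
              n_steps = 100000L, stride = 100L)
  Tm <- mean(r$log$temperature[-seq_len(100L)])  # discard equilibration
  expect_lt(abs(Tm - 310) / 310, 0.02)
})

test_that("runs are deterministic per seed and resumable", {
  sys <- gen_bilayer_patch(60, seed = 7L)
  p <- sim_params(seed = 13L)
  a <- run_cg(sys, p, n_steps = 400L, stride = 100L)
  b <- run_cg(sys, p, n_steps = 400L, stride = 100L)
  expect_identical(a$system$x, b$system$x)
  expect_identical(a$traj, b$traj)

  ## resuming from a checkpoint reproduces the long run bit-for-bit
  half <- run_cg(sys, p, n_steps = 200L, stride = 100L)
  rest <- run_cg(half$system, p, n_steps = 200L, stride = 100L,
                 v0 = half$v, step0 = half$steps_done)
  expect_identical(rest$system$x, a$system$x)
})

test_that("integration blow-up is detected", {
  sys <- gen_bilayer_patch(60, seed = 7L)
  expect_error(run_cg(sys, sim_params(dt = 5e4, damping = Inf),
                      n_steps = 50L, stride = 10L),
               "blew up|overlap")
})
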