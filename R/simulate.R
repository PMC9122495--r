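## R surface of the CG simulation engine: parameters, pair potentials,
## force evaluation, Langevin dynamics.

#' Simulation parameters
#'
#' Defaults follow the CG production protocol: 50 fs time step, Langevin
#' thermostat at 310 K with a 100 ps coupling constant, 1.5 nm nonbonded
#' cutoff.
#'
#' @param dt Time step in fs (default 50).
#' @param temperature Temperature in K (default 310).
#' @param damping Langevin coupling constant in fs (default 1e5 = 100 ps);
#'   `Inf` disables friction and noise (plain velocity-Verlet NVE).
#' @param cutoff Nonbonded cutoff in nm (default 1.5).
#' @param sigma,eps_rep,eps_att Nonbonded pair-potential family: bead
#'   diameter (nm), repulsive-core strength and attractive well depth
#'   (kcal/mol) at scaling factor 1.
#' @param seed Integer RNG seed for the thermostat noise.
#' @param use_cells Use the cell-list neighbour search (results are
#'   independent of this switch; all-pairs is kept for testing).
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(dt = 50, temperature = 310, damping = 1e5,
                       cutoff = 1.5, sigma = 0.68, eps_rep = 0.5,
                       eps_att = 0.7, seed = 1L, use_cells = TRUE) {
  stopifnot(dt > 0, cutoff > 0, temperature > 0)
  structure(list(dt = dt, temperature = temperature, damping = damping,
                 cutoff = cutoff, sigma = sigma, eps_rep = eps_rep,
                 eps_att = eps_att, seed = as.integer(seed),
                 use_cells = use_cells),
            class = "sim_params")
}

#' Nonbonded pair potential of the CG model
#'
#' A Weeks-Chandler-Andersen repulsive core plus a cosine-squared
#' attractive well that goes smoothly to zero at the cutoff.  The well
#' depth equals `factor * eps_att` exactly, so attraction depth and force
#' scale linearly with the pair's scaling factor; `factor = 0` leaves a
#' purely repulsive potential.
#'
#' @param r Distances in nm (> 0).
#' @param factor Attraction scaling factor (>= 0).
#' @param params A [sim_params()] object (supplies `sigma`, `eps_rep`,
#'   `eps_att`, `cutoff`).
#' @return List with `energy` (kcal/mol) and `force` (kcal/mol/nm,
#'   `-dE/dr`).
#' @export
pair_potential <- function(r, factor = 1, params = sim_params()) {
  if (factor < 0) stop("negative attraction scaling factor")
  pair_potential_cpp(r, factor, params$sigma, params$eps_rep,
                     params$eps_att, params$cutoff)
}

#' Tabulate pair potentials for every interaction-class pair
#'
#' Samples energy and force on a uniform grid over `(r_lo, cutoff]` for
#' each pair of interaction classes, scaled by the interaction table.
#'
#' @param table An [build_interaction_table()] matrix.
#' @param params A [sim_params()].
#' @param n Number of grid points.
#' @param r_lo Smallest tabulated distance, nm.
#' @return Named list (`"A|B"`) of data.frames `r, energy, force`.
#' @export
tabulate_potentials <- function(table, params = sim_params(), n = 1000L,
                                r_lo = 0.05) {
  cls <- rownames(table)
  r <- seq(r_lo, params$cutoff, length.out = n)
  out <- list()
  for (a in seq_along(cls)) for (b in a:length(cls)) {
    pp <- pair_potential(r, table[a, b], params)
    out[[paste(cls[a], cls[b], sep = "|")]] <-
      data.frame(r = r, energy = pp$energy, force = pp$force)
  }
  out
}

.sys_engine_args <- function(sys, table) {
  cls <- as.integer(bead_class(sys)) - 1L
  list(cls = cls,
       fmat = unclass(table),
       mol = sys$mol,
       isprot = is_protein_bead(sys),
       box = if (is.null(sys$box)) numeric(0) else sys$box,
       bonds = as.list(sys$bonds),
       angles = as.list(sys$angles),
       springs = as.list(sys$springs))
}

#' Forces and potential energy of a CG system
#'
#' Sums bonded terms (bonds, angles, elastic springs) and nonbonded pair
#' interactions within the cutoff (minimum image when the system has a
#' box).  Pair forces are antisymmetric by construction.
#'
#' @param sys A `cg_system`.
#' @param table Interaction table (see [build_interaction_table()]).
#' @param params A [sim_params()].
#' @return List with `forces` (n x 3, kcal/mol/nm) and `epot` (kcal/mol).
#' @export
compute_forces <- function(sys, table = build_interaction_table(),
                           params = sim_params()) {
  a <- .sys_engine_args(sys, table)
  cg_forces_cpp(sys$x, a$mol, a$isprot, a$cls, a$fmat,
                params[c("sigma", "eps_rep", "eps_att", "cutoff")],
                a$box, a$bonds, a$angles, a$springs, params$use_cells)
}

#' Relax a CG system by displacement-capped steepest descent
#'
#' Removes bad contacts from freshly built configurations before dynamics:
#' each iteration moves every bead along its force, with per-bead
#' displacements capped at `max_disp`, and backtracks when the energy
#' rises.
#'
#' @param sys A `cg_system`.
#' @param table Interaction table.
#' @param params A [sim_params()].
#' @param n_iter Maximum iterations.
#' @param max_disp Displacement cap per iteration, nm.
#' @param tol Stop when the maximum force (kcal/mol/nm) falls below this.
#' @return The relaxed `cg_system` with attribute `epot`.
#' @export
minimize_cg <- function(sys, table = build_interaction_table(),
                        params = sim_params(), n_iter = 200L,
                        max_disp = 0.02, tol = 50) {
  alpha <- 1e-4
  f <- compute_forces(sys, table, params)
  for (it in seq_len(n_iter)) {
    fmax <- sqrt(max(rowSums(f$forces^2)))
    if (fmax < tol) break
    step <- f$forces * alpha
    nrm <- sqrt(rowSums(step^2))
    scale <- pmin(1, max_disp / pmax(nrm, 1e-12))
    cand <- sys
    cand$x <- sys$x + step * scale
    fc <- compute_forces(cand, table, params)
    if (fc$epot < f$epot) {
      sys <- cand
      f <- fc
      alpha <- alpha * 1.2
    } else {
      alpha <- alpha / 2
    }
  }
  attr(sys, "epot") <- f$epot
  sys
}

#' Run Langevin dynamics on a CG system
#'
#' Underdamped Langevin dynamics via velocity-Verlet with BAOAB splitting:
#' friction `mass / damping` and Gaussian noise satisfying
#' fluctuation-dissipation at the target temperature.  The noise stream is
#' a deterministic function of (seed, step, bead, axis), so identical
#' seeds give bit-identical trajectories and runs can be resumed from the
#' returned state.
#'
#' @param sys A `cg_system`.
#' @param params A [sim_params()].
#' @param n_steps Number of integration steps.
#' @param stride Store a frame and energies every `stride` steps.
#' @param table Interaction table.
#' @param v0 Optional n x 3 initial velocities (nm/fs); default: drawn
#'   from the Maxwell-Boltzmann distribution at the target temperature
#'   (zeroed total momentum), or zero when the thermostat is off.
#' @param step0 Step counter offset (for resuming; use `steps_done` of a
#'   previous run).
#' @return List of class `cg_run`: `system` (with final coordinates),
#'   `v` (final velocities), `traj` (array frames x beads x 3), `log`
#'   (data.frame `step, epot, ekin, temperature`), `steps_done`.
#' @export
run_cg <- function(sys, params = sim_params(), n_steps = 1000L,
                   stride = 100L, table = build_interaction_table(),
                   v0 = NULL, step0 = 0L) {
  n <- n_beads(sys)
  if (is.null(v0)) {
    if (is.finite(params$damping)) {
      set.seed(params$seed)
      vth <- sqrt(.kB * params$temperature / (sys$mass * .mvv2e))
      v0 <- matrix(rnorm(3L * n), n, 3L) * vth
      v0 <- sweep(v0, 2L, colMeans(v0))  # zero total momentum
    } else v0 <- matrix(0, n, 3L)
  }
  a <- .sys_engine_args(sys, table)
  res <- cg_run_cpp(sys$x, v0, sys$mass, a$mol, a$isprot, a$cls, a$fmat,
                    params[c("sigma", "eps_rep", "eps_att", "cutoff")],
                    a$box, a$bonds, a$angles, a$springs,
                    params$dt, params$temperature, params$damping,
                    params$seed, as.integer(n_steps), as.integer(stride),
                    as.integer(step0), params$use_cells)
  sys$x <- res$x
  nstore <- length(res$epot)
  traj <- aperm(array(res$traj, c(3L, n, nstore)), c(3L, 2L, 1L))
  structure(list(system = sys, v = res$v, traj = traj,
                 log = data.frame(step = step0 + stride * seq_len(nstore),
                                  epot = res$epot, ekin = res$ekin,
                                  temperature = res$temperature),
                 steps_done = res$steps_done),
            class = "cg_run")
}

#' @export
print.cg_run <- function(x, ...) {
  cat("cg_run:", x$steps_done, "steps,", dim(x$traj)[1L], "stored frames,",
      n_beads(x$system), "beads\n")
  cat("  mean T =", signif(mean(x$log$temperature), 5), "K; final epot =",
      signif(tail(x$log$epot, 1L), 6), "kcal/mol\n")
  invisible(x)
}
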