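## Position-dependent lateral diffusion of lipids around a membrane protein.
##
## Molecules are classified by their time-averaged planar (XY) distance from
## the protein center into three radial classes (inner / TM / free), and the
## lateral diffusion coefficient is fitted per class from the Einstein
## relation, with block averaging for errors.

#' Radial class specification for position-dependent diffusion
#'
#' @param boundaries Strictly increasing positive distances (nm) separating
#'   the classes; default `c(3.5, 7.0)`: within 3.5 nm of the protein
#'   center (inner zone, about the hydrophobic-helix ring), between 3.5 and
#'   7 nm (TM zone) and beyond 7 nm (protein-free zone).
#' @param labels Class labels, one more than the number of boundaries.
#' @return Object of class `radial_class_spec`.
#' @export
radial_class_spec <- function(boundaries = c(3.5, 7.0),
                              labels = c("inner", "TM", "free")) {
  stopifnot(all(boundaries > 0), !is.unsorted(boundaries, strictly = TRUE),
            length(labels) == length(boundaries) + 1L)
  structure(list(boundaries = boundaries, labels = labels),
            class = "radial_class_spec")
}

#' Lateral trajectory container
#'
#' @param coords 3d array, frames x molecules x 3 (nm), unwrapped
#'   (non-imaged) coordinates.
#' @param dt_us Time between stored frames in microseconds.
#' @param species Character vector per molecule (recycled if length 1).
#' @param masses Optional per-molecule masses (g/mol, default 1).
#' @return Object of class `lateral_traj`.
#' @export
lateral_traj <- function(coords, dt_us, species = "lipid", masses = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3L] == 3L, dt_us > 0)
  n <- dim(coords)[2L]
  structure(list(coords = coords, dt_us = dt_us,
                 species = rep_len(species, n),
                 masses = if (is.null(masses)) rep(1, n) else masses),
            class = "lateral_traj")
}

#' Recenter a trajectory on a reference selection
#'
#' Translates every frame so that the mass-weighted center of the reference
#' selection sits at the origin; all diffusion measured afterwards is
#' relative to that reference (e.g. the protein's lumenal domain).
#'
#' @param traj A [lateral_traj()] object.
#' @param ref Integer or logical index of the reference molecules/particles.
#' @return The recentered `lateral_traj`.
#' @export
recenter <- function(traj, ref) {
  ref <- seq_len(dim(traj$coords)[2L])[ref]
  if (length(ref) == 0L) stop("empty reference selection")
  w <- traj$masses[ref] / sum(traj$masses[ref])
  for (ax in 1:3) {
    com <- traj$coords[, ref, ax, drop = FALSE]
    com <- as.matrix(com[, , 1L]) %*% w
    traj$coords[, , ax] <- traj$coords[, , ax] - as.vector(com)
  }
  traj
}

#' Classify molecules into radial zones
#'
#' Assigns each molecule a class from its time-averaged planar (XY)
#' distance to the origin of a recentered trajectory.  Boundary ties go to
#' the inner class.
#'
#' @param traj A recentered [lateral_traj()].
#' @param spec A [radial_class_spec()].
#' @param frames Optional frame subset to average over.
#' @return Factor of class labels, one per molecule.
#' @export
classify_molecules <- function(traj, spec = radial_class_spec(),
                               frames = NULL) {
  co <- traj$coords
  if (!is.null(frames)) co <- co[frames, , , drop = FALSE]
  nf <- dim(co)[1L]; nm <- dim(co)[2L]
  xs <- matrix(co[, , 1L], nrow = nf, ncol = nm)
  ys <- matrix(co[, , 2L], nrow = nf, ncol = nm)
  rxy <- colMeans(sqrt(xs^2 + ys^2))
  ## intervals are (b_i, b_{i+1}]: a molecule exactly on a boundary is
  ## assigned to the inner class
  cls <- findInterval(rxy, spec$boundaries, left.open = TRUE) + 1L
  factor(spec$labels[cls], levels = spec$labels)
}

#' Time- and ensemble-averaged planar mean squared displacement
#'
#' @param traj A [lateral_traj()] with unwrapped coordinates.
#' @param molecules Index of molecules to include (default all).
#' @param max_lag Maximum lag in frames (must be < number of frames).
#' @param frames Optional frame subset (a contiguous block).
#' @return data.frame with `lag` (frames), `tau_us` and `msd` (nm^2);
#'   `msd[lag = 0] = 0`.
#' @export
msd <- function(traj, molecules = NULL, max_lag = NULL, frames = NULL) {
  co <- traj$coords
  if (!is.null(frames)) co <- co[frames, , , drop = FALSE]
  if (!is.null(molecules)) co <- co[, molecules, , drop = FALSE]
  nf <- dim(co)[1L]
  if (is.null(max_lag)) max_lag <- nf %/% 2L
  if (max_lag >= nf) stop("max_lag must be smaller than the trajectory length")
  if (dim(co)[2L] == 0L) stop("no molecules selected for MSD")
  out <- numeric(max_lag + 1L)
  for (lag in seq_len(max_lag)) {
    dx <- co[(1L + lag):nf, , 1L, drop = FALSE] - co[1:(nf - lag), , 1L, drop = FALSE]
    dy <- co[(1L + lag):nf, , 2L, drop = FALSE] - co[1:(nf - lag), , 2L, drop = FALSE]
    out[lag + 1L] <- mean(dx^2 + dy^2)
  }
  data.frame(lag = 0:max_lag, tau_us = (0:max_lag) * traj$dt_us, msd = out)
}

#' Fit a lateral diffusion coefficient from an MSD curve
#'
#' Least-squares line over the fit window; `D = slope / (2 * dims)` by the
#' Einstein relation (planar displacements, `dims = 2`).
#'
#' @param msd_curve data.frame from [msd()].
#' @param fit_window Length-2 fractions of the maximum lag delimiting the
#'   fit window (default `c(0.1, 0.5)`), or an integer vector of lags.
#' @param dims Dimensionality of the displacements (default 2).
#' @return List with `D` (nm^2/us), `slope`, `intercept`, `window` (lags).
#' @export
fit_diffusion <- function(msd_curve, fit_window = c(0.1, 0.5), dims = 2L) {
  maxlag <- max(msd_curve$lag)
  lags <- if (length(fit_window) == 2L && all(fit_window <= 1))
    seq(max(1L, floor(fit_window[1] * maxlag)), ceiling(fit_window[2] * maxlag))
  else as.integer(fit_window)
  sel <- msd_curve$lag %in% lags
  if (sum(sel) < 2L) stop("degenerate fit window (< 2 points)")
  fit <- lm(msd ~ tau_us, data = msd_curve[sel, ])
  list(D = unname(coef(fit)[2L]) / (2 * dims),
       slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       window = range(lags))
}

#' Detect confined (plateaued) mean squared displacement
#'
#' Compares the slope of the late-lag portion of the MSD curve with the
#' early-lag slope; a late/early slope ratio below `ratio` flags
#' confinement (MSD levelling off at later times, as for lipids trapped
#' inside the seipin ring).
#'
#' @param msd_curve data.frame from [msd()].
#' @param ratio Threshold on late/early slope (default 0.2).
#' @return Logical flag, with the two slopes as attributes.
#' @export
detect_confinement <- function(msd_curve, ratio = 0.2) {
  n <- nrow(msd_curve)
  early <- msd_curve[2:max(3L, floor(0.2 * n)), ]
  late <- msd_curve[floor(0.7 * n):n, ]
  s_e <- coef(lm(msd ~ tau_us, early))[2L]
  s_l <- coef(lm(msd ~ tau_us, late))[2L]
  structure(unname(s_l < ratio * s_e),
            slope_early = unname(s_e), slope_late = unname(s_l))
}

#' Position-dependent diffusion coefficients with block errors
#'
#' Splits the trajectory into `n_blocks` equal blocks; in each block,
#' molecules are (re)classified by their average XY distance and a lateral
#' diffusion coefficient is fitted per species x class.  The mean and
#' standard error over blocks are reported.
#'
#' @param traj A recentered [lateral_traj()].
#' @param spec A [radial_class_spec()].
#' @param n_blocks Number of blocks (default 3).
#' @param max_lag_frac Maximum MSD lag as a fraction of block length.
#' @param fit_window Passed to [fit_diffusion()].
#' @return data.frame with `species`, `class`, `D` (nm^2/us), `D_se`,
#'   `n_molecules` (mean per block), `n_blocks_used`.
#' @export
position_dependent_D <- function(traj, spec = radial_class_spec(),
                                 n_blocks = 3L, max_lag_frac = 0.4,
                                 fit_window = c(0.1, 0.5)) {
  nf <- dim(traj$coords)[1L]
  stopifnot(nf >= n_blocks * 10L)
  n_use <- (nf %/% n_blocks) * n_blocks
  blocks <- split(seq_len(n_use), rep(seq_len(n_blocks), each = n_use / n_blocks))
  species <- unique(traj$species)

  rows <- list()
  for (sp in species) {
    smol <- which(traj$species == sp)
    for (cl in spec$labels) {
      Ds <- c(); ns <- c()
      for (b in blocks) {
        cls <- classify_molecules(traj, spec, frames = b)
        mols <- smol[cls[smol] == cl]
        if (length(mols) == 0L) {
          message("no '", sp, "' molecules in class '", cl,
                  "' for one block; block skipped")
          next
        }
        m <- msd(traj, molecules = mols, frames = b,
                 max_lag = max(3L, floor(max_lag_frac * length(b))))
        Ds <- c(Ds, fit_diffusion(m, fit_window)$D)
        ns <- c(ns, length(mols))
      }
      if (length(Ds) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, class = cl, D = mean(Ds),
        D_se = if (length(Ds) > 1L) sd(Ds) / sqrt(length(Ds)) else NA_real_,
        n_molecules = mean(ns), n_blocks_used = length(Ds))
    }
  }
  do.call(rbind, rows)
}
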