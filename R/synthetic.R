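## Synthetic-data generators: every analysis stage in the package can be
## exercised on data with known ground truth -- flat bilayer patches with
## dissolved or lens-phase TG, TG clusters of controlled shape, Brownian
## walkers with class-dependent diffusion, Gaussian ensembles of known
## spring networks, and an idealized ring-shaped seipin cage.

#' Generate a flat CG bilayer patch with TG
#'
#' Builds a two-leaflet patch of linear four-site PLs on a jittered square
#' lattice.  In `dissolved` mode TG molecules are scattered at the
#' midplane with pairwise separations above the clustering cutoff (every
#' molecule its own cluster); in `lens` mode they form one disc-shaped
#' blob at the midplane (a single cluster by construction).
#'
#' @param n_pl Total number of PL molecules (split over two leaflets).
#' @param tg_percent TG mol% (TG / (TG + PL)); `n_tg` overrides it.
#' @param n_tg Explicit TG count (optional).
#' @param mode `"dissolved"` or `"lens"`.
#' @param apl Area per lipid, nm^2 (sets the patch side).
#' @param spacing Intramolecular bead spacing, nm.
#' @param min_sep Minimum TG-TG center separation in dissolved mode, nm;
#'   the default keeps minimum inter-bead distances above the 2 nm
#'   clustering cutoff (molecule radius ~0.3 nm on each side).
#' @param bond_k,angle_k Bonded parameters as in
#'   [build_spherical_bilayer()].
#' @param box_z Box height, nm.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return A `cg_system` with a `ground_truth` attribute.
#' @export
gen_bilayer_patch <- function(n_pl = 200L, tg_percent = 0, n_tg = NULL,
                              mode = c("dissolved", "lens"), apl = 0.7,
                              spacing = 0.5, min_sep = 2.8, bond_k = 2.5,
                              angle_k = 0.5 * .kB * 310, box_z = 20,
                              seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  n_leaf <- n_pl %/% 2L
  n_pl <- 2L * n_leaf
  if (is.null(n_tg)) n_tg <- round(n_pl * tg_percent / (100 - tg_percent))
  side <- ceiling(sqrt(n_leaf))
  L <- side * sqrt(apl)
  grid <- expand.grid(ix = seq_len(side) - 0.5, iy = seq_len(side) - 0.5)
  grid <- grid[seq_len(n_leaf), ] * sqrt(apl)

  xs <- NULL; types <- character(0); mol <- integer(0)
  mk_leaflet <- function(sign, mol0) {
    zz <- sign * (spacing * (0:3) + 0.25)  # tails at |z| ~ 0.25, heads outermost
    zz <- rev(zz)  # head first
    for (m in seq_len(n_leaf)) {
      jit <- runif(2, -0.08, 0.08)
      xs <<- rbind(xs, cbind(grid$ix[m] + jit[1], grid$iy[m] + jit[2], zz))
      types <<- c(types, c("PL_head", "PL_int", "PL_tail", "PL_tail"))
      mol <<- c(mol, rep(mol0 + m, 4L))
    }
  }
  mk_leaflet(+1, 0L)
  mk_leaflet(-1, n_leaf)

  if (n_tg > 0L) {
    if (mode == "dissolved") {
      per_side <- floor(L / min_sep)
      if (per_side^2 < n_tg)
        stop("cannot place ", n_tg, " dissolved TG molecules ", min_sep,
             " nm apart in a ", signif(L, 3), " nm patch; ",
             "use mode = 'lens' or a larger patch")
      slots <- expand.grid(ix = seq_len(per_side) - 0.5,
                           iy = seq_len(per_side) - 0.5) * min_sep
      slots <- slots[sample.int(nrow(slots), n_tg), , drop = FALSE]
      centers <- cbind(slots$ix, slots$iy, runif(n_tg, -0.3, 0.3))
      ## compact molecules: beads within 0.25 nm of the center keep
      ## intermolecular min-bead distances above the cutoff
      rad <- 0.25
    } else {
      disc_r <- 0.35 * sqrt(n_tg)  # tight disc at the midplane
      ang <- runif(n_tg, 0, 2 * pi)
      rr <- disc_r * sqrt(runif(n_tg))
      centers <- cbind(L / 2 + rr * cos(ang), L / 2 + rr * sin(ang),
                       runif(n_tg, -0.4, 0.4))
      rad <- 0.3
    }
    for (m in seq_len(n_tg)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      tb <- .tangent_basis(u)
      pos <- rbind(centers[m, ],
                   centers[m, ] + rad * u,
                   centers[m, ] + rad * tb$a,
                   centers[m, ] + rad * tb$b)
      xs <- rbind(xs, pos)
      types <- c(types, c("TG_gly", rep("TG_tail", 3L)))
      mol <- c(mol, rep(n_pl + m, 4L))
    }
  }

  ## drop PL molecules overlapping a TG bead so the patch is directly
  ## usable as a simulation start
  if (n_tg > 0L) {
    tg_rows <- which(mol > n_pl)
    txs <- t(xs[tg_rows, , drop = FALSE])
    bad <- logical(n_pl)
    for (m in seq_len(n_pl)) {
      rows <- which(mol == m)
      d2 <- min(vapply(rows, function(r)
        min(colSums((txs - xs[r, ])^2)), 0))
      bad[m] <- d2 < 0.45^2
    }
    if (any(bad)) {
      keep <- !(mol %in% which(bad))
      xs <- xs[keep, , drop = FALSE]
      types <- types[keep]
      oldmol <- mol[keep]
      mol <- match(oldmol, unique(oldmol))
      n_removed <- sum(bad)
      n_pl <- n_pl - n_removed
    }
  }

  nb <- nrow(xs)
  first <- seq(1L, nb, by = 4L)
  pl_first <- first[seq_len(n_pl)]
  bonds <- data.frame(i = rep(pl_first, each = 3L) + 0:2,
                      j = rep(pl_first, each = 3L) + 1:3,
                      k = bond_k, r0 = spacing)
  if (n_tg > 0L) {
    tg_first <- first[n_pl + seq_len(n_tg)]
    bonds <- rbind(bonds,
                   data.frame(i = rep(tg_first, each = 3L),
                              j = rep(tg_first, each = 3L) + 1:3,
                              k = bond_k, r0 = 0.3))
  }
  angles <- data.frame(i = rep(pl_first, each = 2L) + 0:1,
                       j = rep(pl_first, each = 2L) + 1:2,
                       l = rep(pl_first, each = 2L) + 2:3,
                       k = angle_k, theta0 = pi)
  xs[, 3L] <- xs[, 3L] + box_z / 2
  sys <- cg_system(xs, types, mol, bonds = bonds, angles = angles,
                   box = c(L, L, box_z))
  attr(sys, "ground_truth") <- list(kind = "bilayer_patch", mode = mode,
                                    n_pl = n_pl, n_tg = n_tg, seed = seed)
  sys
}

#' Generate a TG cluster of controlled shape
#'
#' Samples points uniformly inside a sphere, a thin disc or a rod
#' (cylinder), for exercising the shape-anisotropy statistic: a sphere has
#' anisotropy 0, a thin disc 0.25, a thin rod 1.
#'
#' @param shape `"sphere"`, `"disc"` or `"rod"`.
#' @param n Number of points (>= 4).
#' @param size Radius (sphere, disc) or half-length (rod), nm.
#' @param thickness Disc thickness or rod diameter, nm.
#' @param seed RNG seed.
#' @return n x 3 coordinate matrix with a `ground_truth` attribute.
#' @export
gen_tg_cluster <- function(shape = c("sphere", "disc", "rod"), n = 1000L,
                           size = 5, thickness = 0.005, seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(n >= 4L)
  set.seed(seed)
  x <- switch(shape,
    sphere = {
      u <- matrix(rnorm(3L * n), n, 3L)
      u <- u / sqrt(rowSums(u^2))
      u * size * runif(n)^(1 / 3)
    },
    disc = {
      r <- size * sqrt(runif(n))
      a <- runif(n, 0, 2 * pi)
      cbind(r * cos(a), r * sin(a), runif(n, -thickness / 2, thickness / 2))
    },
    rod = {
      r <- thickness / 2 * sqrt(runif(n))
      a <- runif(n, 0, 2 * pi)
      cbind(runif(n, -size, size), r * cos(a), r * sin(a))
    })
  attr(x, "ground_truth") <- list(kind = "tg_cluster", shape = shape,
                                  n = n, size = size,
                                  thickness = thickness, seed = seed)
  x
}

#' Generate 2D Brownian walkers with class-dependent diffusion
#'
#' Independent Gaussian increments with per-axis variance `2 D dt`; an
#' optional harmonic trap (Ornstein-Uhlenbeck dynamics) produces the MSD
#' plateau characteristic of confined lipids.  z coordinates are kept at 0.
#'
#' @param n_walkers Walkers per class.
#' @param D Named vector of diffusion coefficients per class, nm^2/us.
#' @param n_frames Number of stored frames.
#' @param dt_us Frame spacing in microseconds.
#' @param trap Harmonic trap stiffness kappa (1/us units: increments are
#'   damped by `exp(-kappa dt)` toward the walker's origin); 0 = free.
#' @param origin_sd Spread of the walkers' starting points, nm.
#' @param seed RNG seed.
#' @return A [lateral_traj()] with species = class labels and ground truth
#'   in attribute `ground_truth`.
#' @export
gen_brownian <- function(n_walkers = 100L, D = c(free = 1.0), n_frames = 500L,
                         dt_us = 0.01, trap = 0, origin_sd = 0, seed = 1L) {
  stopifnot(all(D >= 0), n_frames >= 2L)
  set.seed(seed)
  classes <- names(D)
  if (is.null(classes)) classes <- paste0("class", seq_along(D))
  ntot <- n_walkers * length(D)
  co <- array(0, c(n_frames, ntot, 3L))
  species <- rep(classes, each = n_walkers)
  for (ci in seq_along(D)) {
    idx <- (ci - 1L) * n_walkers + seq_len(n_walkers)
    sdd <- sqrt(2 * D[ci] * dt_us)
    x0 <- matrix(rnorm(2L * n_walkers, 0, origin_sd), n_walkers, 2L)
    pos <- x0
    co[1L, idx, 1:2] <- pos
    damp <- exp(-trap * dt_us)
    for (f in 2:n_frames) {
      pos <- (pos - x0) * damp + x0 +
        matrix(rnorm(2L * n_walkers, 0, sdd), n_walkers, 2L)
      co[f, idx, 1:2] <- pos
    }
  }
  tr <- lateral_traj(co, dt_us, species)
  attr(tr, "ground_truth") <- list(kind = "brownian", D = D, trap = trap,
                                   n_walkers = n_walkers, seed = seed)
  tr
}

#' Sample a Gaussian ensemble from a harmonic spring network
#'
#' Draws equilibrium configurations of the elastic network (energy
#' `sum k (r - r0)^2`) at temperature T from its normal modes, with the
#' rigid-body null space removed, so the sample covariance converges to
#' the analytic network covariance.  The network must be connected.
#'
#' @param x n x 3 reference coordinates (nm).
#' @param springs data.frame `i, j, k, r0` (k in kcal/mol/A^2).
#' @param temperature Temperature in K.
#' @param n_samples Number of samples.
#' @param seed RNG seed.
#' @return 3d array: samples x beads x 3, with `ground_truth` attribute.
#' @export
gen_gaussian_ensemble <- function(x, springs, temperature = 310,
                                  n_samples = 1000L, seed = 1L) {
  x <- as.matrix(x)
  g <- igraph::graph_from_edgelist(cbind(springs$i, springs$j),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(x) - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop("spring network is disconnected: components of sizes ",
         paste(comp$csize, collapse = ", "))
  set.seed(seed)
  nc <- network_covariance(x, springs, temperature)
  amp <- sqrt(.kB * temperature / nc$values)
  n <- nrow(x)
  ens <- array(0, c(n_samples, n, 3L))
  for (s in seq_len(n_samples)) {
    xi <- rnorm(length(amp))
    dx <- nc$vectors %*% (amp * xi)
    ens[s, , ] <- x + matrix(dx, n, 3L, byrow = TRUE)
  }
  attr(ens, "ground_truth") <- list(kind = "gaussian_ensemble",
                                    springs = springs,
                                    temperature = temperature, seed = seed)
  ens
}

#' Generate an idealized ring-shaped seipin cage
#'
#' Builds a C_n-symmetric CG cage in the flat-membrane frame (z = 0 at the
#' bilayer midplane, cytosol at +z): per subunit a lumenal-domain blob
#' (below the membrane), a hydrophobic-helix (HH) arc at the lumenal
#' leaflet depth with 2 TG-attractive beads, and two TM segments rising
#' from the lumenal domain to the cytosolic surface with 4 TG-attractive
#' central beads each and a flagged terminal tip.  The default bead budget
#' is 61 per subunit (38 lumenal + 5 HH + 2 x 9 TM), matching the
#' 4-residues-per-bead mapping of the Arg23-Arg265 construct.
#'
#' @param n_subunits Number of subunits (11 for the human seipin
#'   undecamer; 1 gives the single-subunit control).
#' @param hh_radius HH ring radius, nm (default 2).
#' @param lum_radius Mid radius of the lumenal-domain ring, nm.
#' @param tip_radius Radius of the TM tip ring, nm (default 7: a 14 nm
#'   neck, inside the experimentally measured 13-17 nm range).
#' @param half_thickness Membrane half thickness, nm (tips sit at +z =
#'   `half_thickness`).
#' @param jitter Placement jitter (nm) applied to bead positions.
#' @param seed RNG seed for the jitter.
#' @return A `cg_system` of `PROT` beads with all annotation flags set and
#'   one molecule/subunit id per subunit.
#' @export
gen_idealized_seipin <- function(n_subunits = 11L, hh_radius = 2.0,
                                 lum_radius = 3.1, tip_radius = 7.0,
                                 half_thickness = 2.0, jitter = 0.03,
                                 seed = 1L) {
  stopifnot(n_subunits >= 1L, hh_radius > 0, tip_radius > hh_radius)
  set.seed(seed)
  sector <- 2 * pi / max(n_subunits, 11L)  # subunit footprint of the 11-mer

  one_subunit <- function(phi0) {
    pol <- function(r, dphi, z)
      c(r * cos(phi0 + dphi), r * sin(phi0 + dphi), z)
    pos <- list(); flag <- list()
    add <- function(p, ...) {
      pos[[length(pos) + 1L]] <<- p
      flag[[length(flag) + 1L]] <<- list(...)
    }
    ## lumenal domain: 38 beads in a 3-radius x 3-depth x 4-arc block + 2
    rr <- lum_radius + c(-0.5, 0, 0.5)
    zz <- c(-2.6, -3.1, -3.6)
    aa <- seq(-0.3, 0.3, length.out = 4L) * sector
    cnt <- 0L
    for (r in rr) for (z in zz) for (a in aa) {
      add(pol(r, a, z)); cnt <- cnt + 1L
    }
    add(pol(lum_radius, -0.1 * sector, -4.0))
    add(pol(lum_radius, +0.1 * sector, -4.0))
    ## HH arc: 5 beads at the lumenal leaflet depth; 2 attract TG
    ha <- seq(-0.3, 0.3, length.out = 5L) * sector
    for (k in seq_along(ha))
      add(pol(hh_radius, ha[k], -0.65 * half_thickness),
          tg_attract_hh = k %in% c(2L, 4L), interfacial = TRUE)
    ## two TM segments: 9 beads from the lumenal rim to the cytosolic tip
    for (side in c(-1, 1)) {
      t <- seq(0, 1, length.out = 9L)
      rs <- lum_radius + (tip_radius - lum_radius) * t
      zsg <- -half_thickness + 2 * half_thickness * t
      for (k in 1:9)
        add(pol(rs[k], side * 0.32 * sector, zsg[k]),
            tm_segment = TRUE,
            tg_attract_tm = k %in% 4:7,
            tm_tip = k == 9L,
            hydrophobic_phase = abs(zsg[k]) < 0.5 * half_thickness,
            interfacial = abs(zsg[k]) >= 0.5 * half_thickness &
                          abs(zsg[k]) <= 1.1 * half_thickness)
    }
    list(x = do.call(rbind, pos), flags = flag)
  }

  xs <- NULL; sub <- integer(0)
  fl <- lapply(setNames(.flag_names, .flag_names), function(f) logical(0))
  for (s in seq_len(n_subunits)) {
    su <- one_subunit(2 * pi * (s - 1L) / n_subunits)
    nb <- nrow(su$x)
    xs <- rbind(xs, su$x + matrix(rnorm(3L * nb, 0, jitter), nb, 3L))
    sub <- c(sub, rep(s, nb))
    for (f in .flag_names) {
      v <- vapply(su$flags, function(fv) isTRUE(fv[[f]]), FALSE)
      fl[[f]] <- c(fl[[f]], v)
    }
  }
  ## TM central beads sit in the hydrophobic phase as well
  sys <- cg_system(xs, rep("PROT", nrow(xs)), mol = sub, subunit = sub,
                   flags = fl)
  attr(sys, "ground_truth") <- list(kind = "idealized_seipin",
                                    n_subunits = n_subunits,
                                    hh_radius = hh_radius,
                                    tip_radius = tip_radius, seed = seed)
  sys
}
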