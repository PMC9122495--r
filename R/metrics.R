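## Oil-lens morphology metrics: TG clustering, nucleation percentage,
## shape anisotropy, ER-LD neck diameter, RMSF, and time-series event
## tagging (coalescence vs Ostwald ripening).

#' Single-linkage clustering of TG molecules
#'
#' Two TG molecules belong to the same cluster when their minimum
#' inter-bead distance is below `cutoff` (default 2 nm); clusters are the
#' connected components of that graph, so two oil lenses that come within
#' the cutoff of each other are counted as one.
#'
#' @param x Bead coordinate matrix (n x 3, nm) of the TG beads, or a
#'   `cg_system` (TG beads are selected automatically), or a
#'   `grouped_frame` (TG groups selected).
#' @param mol Integer molecule id per bead (not needed for the object
#'   inputs).
#' @param cutoff Clustering cutoff in nm (default 2).
#' @param box Optional periodic box (nm) for minimum-image distances.
#' @return List of class `cluster_result`: `labels` (per molecule,
#'   named by molecule id), `sizes`, `largest` (cluster id), `n_molecules`.
#' @export
cluster_tg <- function(x, mol = NULL, cutoff = 2.0, box = NULL) {
  if (inherits(x, "cg_system")) {
    sel <- x$type %in% c("TG_gly", "TG_tail")
    mol <- x$mol[sel]
    if (is.null(box)) box <- x$box
    x <- x$x[sel, , drop = FALSE]
  } else if (inherits(x, "grouped_frame")) {
    sel <- x$mol_kind == "TG"
    mol <- x$mol_id[sel]
    if (is.null(box)) box <- attr(x, "box")
    x <- cbind(x$x[sel], x$y[sel], x$z[sel])
  }
  if (is.null(mol) || length(mol) != nrow(x))
    stop("need one molecule id per bead")
  if (length(mol) == 0L) stop("no TG molecules to cluster")

  mols <- unique(mol)
  nm <- length(mols)
  mi <- match(mol, mols)

  ## molecule-molecule minimum bead distance, thresholded
  if (is.null(box)) {
    db <- as.matrix(stats::dist(x))
  } else {
    db <- matrix(0, nrow(x), nrow(x))
    for (ax in 1:3) {
      d <- outer(x[, ax], x[, ax], "-")
      d <- d - box[ax] * round(d / box[ax])
      db <- db + d^2
    }
    db <- sqrt(db)
  }
  close <- which(db < cutoff, arr.ind = TRUE)
  close <- close[mi[close[, 1L]] < mi[close[, 2L]], , drop = FALSE]
  edges <- unique(cbind(mi[close[, 1L]], mi[close[, 2L]]))

  g <- igraph::make_empty_graph(n = nm, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  labels <- comp$membership
  names(labels) <- mols
  sizes <- as.vector(table(labels))
  structure(list(labels = labels, sizes = sizes,
                 largest = which.max(sizes), n_molecules = nm),
            class = "cluster_result")
}

#' Nucleation percentage
#'
#' The percentage of TG molecules belonging to the largest TG cluster.
#'
#' @param result A `cluster_result` from [cluster_tg()].
#' @param n_total Total number of TG molecules (default: those clustered).
#' @return Percentage in `[0, 100]`.
#' @export
nucleation_percentage <- function(result, n_total = result$n_molecules) {
  stopifnot(n_total >= 1)
  100 * max(result$sizes) / n_total
}

#' Relative shape anisotropy of a cluster
#'
#' Computes the (mass-weighted) gyration tensor of the cluster beads and
#' returns the relative shape anisotropy
#' `kappa^2 = 3/2 * (l1^2 + l2^2 + l3^2) / (l1 + l2 + l3)^2 - 1/2`
#' from its eigenvalues.  A sphere gives 0, a thin planar disc 0.25 and a
#' line 1.
#'
#' @param x Bead coordinates (n x 3, nm).
#' @param mass Optional per-bead masses.
#' @return Anisotropy in `[0, 1]`.
#' @export
anisotropy <- function(x, mass = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("anisotropy needs at least 2 beads")
  if (is.null(mass)) mass <- rep(1, nrow(x))
  w <- mass / sum(mass)
  ctr <- colSums(x * w)
  xc <- sweep(x, 2L, ctr)
  S <- t(xc * w) %*% xc
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(lam)
  if (tr <= .Machine$double.eps)
    stop("degenerate gyration tensor: all beads coincide")
  1.5 * sum(lam^2) / tr^2 - 0.5
}

#' ER-LD neck diameter from the TM terminal tips
#'
#' The neck is approximated by the circle formed by the terminal beads of
#' the N- and C-terminal TM segments: twice the mean in-plane radial
#' distance of the tip beads from the complex's principal axis through its
#' center of mass.  For the ring-shaped seipin complex the symmetry axis is
#' the gyration-tensor eigenvector with the smallest eigenvalue.
#'
#' @param sys A `cg_system` (tips = beads flagged `tm_tip`), or a tip
#'   coordinate matrix (n x 3, nm).
#' @param axis Optional axis (length-3); default: principal axis of the
#'   protein beads (or of the tips themselves for a bare matrix).
#' @return Neck diameter in nm.
#' @export
neck_diameter <- function(sys, axis = NULL) {
  if (inherits(sys, "cg_system")) {
    tips <- sys$x[sys$flags$tm_tip, , drop = FALSE]
    ref <- sys$x[sys$type == "PROT", , drop = FALSE]
  } else {
    tips <- as.matrix(sys)
    ref <- tips
  }
  if (nrow(tips) < 3L) stop("need at least 3 TM tip beads")
  if (is.null(axis)) {
    rc <- sweep(ref, 2L, colMeans(ref))
    S <- t(rc) %*% rc / nrow(rc)
    e <- eigen(S, symmetric = TRUE)
    axis <- e$vectors[, 3L]  # smallest eigenvalue: ring symmetry axis
  }
  axis <- axis / sqrt(sum(axis^2))
  ctr <- colMeans(ref)
  rel <- sweep(tips, 2L, ctr)
  along <- rel %*% axis
  inplane <- rel - along %*% t(axis)
  2 * mean(sqrt(rowSums(inplane^2)))
}

#' Per-bead RMSF of an aligned ensemble
#'
#' @param ensemble 3d array: samples x beads x 3 (nm), rigid-body aligned
#'   (see [align_ensemble()]).
#' @return Numeric vector: per-bead root-mean-square deviation from the
#'   mean position (nm).
#' @export
rmsf <- function(ensemble) {
  stopifnot(length(dim(ensemble)) == 3L)
  if (dim(ensemble)[1L] < 2L) stop("RMSF needs at least 2 samples")
  xbar <- apply(ensemble, c(2L, 3L), mean)
  dev2 <- sweep(ensemble, c(2L, 3L), xbar)^2
  sqrt(apply(dev2, 2L, mean) * 3)  # mean over samples and axes, x3 axes
}

#' Lens metrics time series with event tagging
#'
#' Computes nucleation percentage and anisotropy (and optionally the neck
#' diameter) per frame, then tags candidate growth events: a jump in
#' nucleation percentage above `jump_threshold` within one window marks a
#' coalescence candidate; sustained slow growth over `ripening_window`
#' frames marks an Ostwald-ripening candidate.  The tags are heuristic
#' annotations; thresholds are recorded in the output attributes.
#'
#' @param frames List of `cg_system` frames (or of lists with elements
#'   `x`, `mol` for bare TG coordinates).
#' @param cutoff Clustering cutoff, nm.
#' @param neck Also compute the neck diameter per frame (needs tip flags)?
#' @param jump_threshold Percentage-point jump flagged as coalescence
#'   (default 10).
#' @param ripening_window Number of frames of sustained sub-threshold
#'   growth flagged as ripening (default 5).
#' @return data.frame: `frame`, `nucleation`, `anisotropy`, optional
#'   `neck_diameter`, `event` (`""`, `"coalescence"`, `"ripening"`).
#' @export
metrics_timeseries <- function(frames, cutoff = 2.0, neck = FALSE,
                               jump_threshold = 10, ripening_window = 5L) {
  rows <- lapply(seq_along(frames), function(fi) {
    fr <- frames[[fi]]
    if (inherits(fr, "cg_system")) {
      cl <- cluster_tg(fr, cutoff = cutoff)
      sel <- fr$type %in% c("TG_gly", "TG_tail")
      xs <- fr$x[sel, , drop = FALSE]
      mol <- fr$mol[sel]
    } else {
      cl <- cluster_tg(fr$x, fr$mol, cutoff = cutoff)
      xs <- fr$x; mol <- fr$mol
    }
    big <- names(cl$labels)[cl$labels == cl$largest]
    xs_big <- xs[as.character(mol) %in% big, , drop = FALSE]
    data.frame(frame = fi,
               nucleation = nucleation_percentage(cl),
               anisotropy = if (nrow(xs_big) >= 4L) anisotropy(xs_big)
                            else NA_real_,
               neck_diameter = if (neck && inherits(fr, "cg_system"))
                 neck_diameter(fr) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (!neck) out$neck_diameter <- NULL

  out$event <- ""
  dn <- c(NA, diff(out$nucleation))
  out$event[which(dn > jump_threshold)] <- "coalescence"
  if (nrow(out) > ripening_window) {
    for (i in seq(ripening_window + 1L, nrow(out))) {
      win <- dn[(i - ripening_window + 1L):i]
      if (all(!is.na(win)) && all(win > 0) && all(win <= jump_threshold))
        if (out$event[i] == "") out$event[i] <- "ripening"
    }
  }
  attr(out, "jump_threshold") <- jump_threshold
  attr(out, "ripening_window") <- ripening_window
  out
}
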