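## Elastic-network fluctuation analysis and heterogeneous fluctuation
## matching (hENM).
##
## For the spring energy convention k (r - r0)^2, each spring contributes a
## 1d stiffness of 2k along the bond direction, so a single spring's
## equilibrium distance variance is kB T / (2 k).

## Hessian of the network energy sum k (r - r0)^2 at the reference
## structure x (springs at their rest length), in kcal/mol/nm^2 units.
.network_hessian <- function(x, springs) {
  n <- nrow(x)
  H <- matrix(0, 3L * n, 3L * n)
  for (s in seq_len(nrow(springs))) {
    i <- springs$i[s]; j <- springs$j[s]
    b <- x[j, ] - x[i, ]
    b <- b / sqrt(sum(b^2))
    blk <- 2 * springs$k[s] * 100 * (b %o% b)  # kcal/mol/A^2 -> /nm^2
    ii <- 3L * (i - 1L) + 1:3; jj <- 3L * (j - 1L) + 1:3
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  H
}

#' Thermal covariance and normal modes of an elastic network
#'
#' Diagonalizes the network Hessian (energy convention `k (r - r0)^2`,
#' evaluated at the reference structure) and returns the equilibrium
#' covariance `kB T * H^+` with the rigid-body null space removed.
#'
#' @param x n x 3 reference coordinates (nm).
#' @param springs data.frame `i, j, k, r0` with k in kcal/mol/A^2.
#' @param temperature Temperature in K (default 310).
#' @param mode_tol Relative eigenvalue threshold below which modes are
#'   treated as rigid-body/zero modes.
#' @return List with `C` (3n x 3n covariance, nm^2), `values`, `vectors`
#'   (soft, non-rigid modes only) and `x`.
#' @export
network_covariance <- function(x, springs, temperature = 310,
                               mode_tol = 1e-8) {
  x <- as.matrix(x)
  H <- .network_hessian(x, springs)
  e <- eigen(H, symmetric = TRUE)
  keep <- e$values > mode_tol * max(e$values)
  V <- e$vectors[, keep, drop = FALSE]
  lam <- e$values[keep]
  C <- V %*% (t(V) * (.kB * temperature / lam))
  list(C = C, values = lam, vectors = V, x = x)
}

#' Per-bead RMSF of an elastic network
#'
#' @inheritParams network_covariance
#' @return Numeric vector: per-bead root-mean-square fluctuation (nm),
#'   `sqrt(trace)` of the bead's 3 x 3 covariance block.
#' @export
network_rmsf <- function(x, springs, temperature = 310) {
  nc <- network_covariance(x, springs, temperature)
  n <- nrow(nc$x)
  vapply(seq_len(n), function(i)
    sqrt(sum(diag(nc$C[3L * (i - 1L) + 1:3, 3L * (i - 1L) + 1:3]))), 0)
}

## linearized pair-distance variance from a 3n x 3n covariance
.pair_distance_var <- function(C, x, pairs) {
  vapply(seq_len(nrow(pairs)), function(s) {
    i <- pairs$i[s]; j <- pairs$j[s]
    b <- x[j, ] - x[i, ]
    b <- b / sqrt(sum(b^2))
    ii <- 3L * (i - 1L) + 1:3; jj <- 3L * (j - 1L) + 1:3
    max(0, sum(b * ((C[ii, ii] + C[jj, jj] - C[ii, jj] - C[jj, ii]) %*% b)))
  }, 0)
}

#' Heterogeneous elastic network by iterative fluctuation matching (hENM)
#'
#' Given an aligned ensemble of bead positions, finds per-pair spring
#' constants such that the harmonic network reproduces the ensemble's
#' pairwise distance fluctuations.  Candidate pairs are those with mean
#' distance below `cutoff` (default 1.2 nm, i.e. 12 A).  Spring constants
#' are updated multiplicatively from the ratio of model to target distance
#' variance until the worst relative mismatch falls below `tol`.
#' Optionally, pairs without an hENM spring but with mean distance below
#' `backfill_cutoff` receive a weak `backfill_sc` spring (0.1 kcal/mol/A^2
#' within 11 A in the seipin model).
#'
#' @param ensemble 3d array: samples x beads x 3 (nm), rigid-body aligned.
#' @param cutoff Candidate-pair cutoff on the mean distance, nm.
#' @param backfill Add backfill springs for non-hENM close pairs?
#' @param backfill_sc,backfill_cutoff Backfill constant (kcal/mol/A^2) and
#'   cutoff (nm).
#' @param temperature Temperature in K.
#' @param init_k Initial spring constant, kcal/mol/A^2.
#' @param k_range Admissible spring-constant range (clamped).
#' @param gamma Update damping exponent in (0, 1].
#' @param max_iter,tol Convergence controls (worst relative variance
#'   mismatch).
#' @return data.frame `i, j, k, r0` (k in kcal/mol/A^2, r0 = mean
#'   distance, nm) with attributes `residual` (final worst relative
#'   mismatch), `iterations`, and `x` (mean structure).
#' @export
build_henm <- function(ensemble, cutoff = 1.2, backfill = FALSE,
                       backfill_sc = 0.1, backfill_cutoff = 1.1,
                       temperature = 310, init_k = 0.5,
                       k_range = c(1e-4, 100), gamma = 0.6,
                       max_iter = 200L, tol = 1e-3) {
  stopifnot(length(dim(ensemble)) == 3L, dim(ensemble)[3L] == 3L)
  ns <- dim(ensemble)[1L]; n <- dim(ensemble)[2L]
  if (ns < 100L) stop("need at least 100 ensemble samples for hENM")
  xbar <- apply(ensemble, c(2L, 3L), mean)

  ## mean distances and distance variances from the ensemble
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dists <- matrix(0, ns, nrow(pairs))
  for (s in seq_len(ns)) {
    fr <- ensemble[s, , , drop = TRUE]
    dm <- as.matrix(stats::dist(fr))
    dists[s, ] <- dm[pairs]
  }
  dbar <- colMeans(dists)
  dvar <- apply(dists, 2L, var)

  cand <- which(dbar < cutoff)
  if (length(cand) == 0L) stop("no candidate pairs within the hENM cutoff")
  if (any(dvar[cand] <= .Machine$double.eps)) {
    warning("rigid pair(s) with zero distance fluctuation; ",
            "their spring constants are capped at the upper bound")
    dvar[cand][dvar[cand] <= .Machine$double.eps] <-
      .kB * temperature / (2 * k_range[2L] * 100)
  }

  springs <- data.frame(i = pairs[cand, 1L], j = pairs[cand, 2L],
                        k = init_k, r0 = dbar[cand])
  target <- dvar[cand]

  it <- 0L; resid <- Inf
  while (it < max_iter) {
    it <- it + 1L
    nc <- network_covariance(xbar, springs, temperature)
    model <- .pair_distance_var(nc$C, xbar, springs)
    ratio <- model / target
    resid <- max(abs(ratio - 1))
    if (resid < tol) break
    springs$k <- pmin(pmax(springs$k * ratio^gamma, k_range[1L]), k_range[2L])
  }
  if (resid >= tol && all(springs$k < k_range[2L] - 1e-9) && resid > 0.05)
    stop("hENM fluctuation matching did not converge after ", max_iter,
         " iterations (worst relative mismatch ", signif(resid, 3), ")")

  if (backfill) {
    bf <- setdiff(which(dbar < backfill_cutoff), cand)
    if (length(bf))
      springs <- rbind(springs,
                       data.frame(i = pairs[bf, 1L], j = pairs[bf, 2L],
                                  k = backfill_sc, r0 = dbar[bf]))
  }
  attr(springs, "residual") <- resid
  attr(springs, "iterations") <- it
  attr(springs, "x") <- xbar
  springs
}

#' Rigid-body (Kabsch) alignment of an ensemble
#'
#' Aligns every sample onto the first (or a given reference) by optimal
#' rotation and translation.
#'
#' @param ensemble 3d array: samples x beads x 3.
#' @param ref Reference coordinates (default: first sample).
#' @return The aligned ensemble (same shape).
#' @export
align_ensemble <- function(ensemble, ref = NULL) {
  ns <- dim(ensemble)[1L]
  if (is.null(ref)) ref <- ensemble[1L, , , drop = TRUE]
  ref <- sweep(ref, 2L, colMeans(ref))
  for (s in seq_len(ns)) {
    fr <- ensemble[s, , , drop = TRUE]
    fr <- sweep(fr, 2L, colMeans(fr))
    sv <- svd(t(fr) %*% ref)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    ensemble[s, , ] <- fr %*% t(R)
  }
  ensemble
}
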