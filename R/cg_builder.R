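## Builder for the highly coarse-grained seipin/lipid model: 4 residues per
## protein bead, 4-site lipids, elastic networks, attraction scaling table,
## spherical bilayers and protein embedding.

#' Map a protein to CG beads at 4 residues per bead
#'
#' Consecutive blocks of four residues are mapped to one bead at their
#' mass-weighted center; a final partial block forms its own bead.  For the
#' seipin construct spanning Arg23-Arg265 (243 residues per subunit) this
#' yields 61 beads per subunit.
#'
#' @param residues data.frame with columns `subunit`, `resid`, `x`, `y`,
#'   `z` (nm) and optionally `mass`; residues must be consecutive within
#'   each subunit and the residue range identical across subunits.
#' @param block Residues per bead (default 4).
#' @return A `cg_system` of `PROT` beads (one molecule per subunit), no
#'   bonds; connectivity is added by [build_enm()] / [build_henm()].
#' @export
#' @examples
#' res <- data.frame(subunit = 1, resid = 23:265,
#'                   x = rnorm(243), y = rnorm(243), z = rnorm(243))
#' n_beads(map_protein_cg(res))  # 61
map_protein_cg <- function(residues, block = 4L) {
  stopifnot(all(c("subunit", "resid", "x", "y", "z") %in% names(residues)))
  if (is.null(residues$mass)) residues$mass <- 110  # average residue mass
  subs <- sort(unique(residues$subunit))
  ref_res <- sort(residues$resid[residues$subunit == subs[1L]])
  xs <- list(); sub_id <- integer(0)
  for (s in subs) {
    d <- residues[residues$subunit == s, , drop = FALSE]
    d <- d[order(d$resid), , drop = FALSE]
    if (!identical(sort(d$resid), ref_res) ||
        any(diff(d$resid) != 1L))
      stop("subunit ", s, " is missing residues or differs from subunit ",
           subs[1L], " (expected consecutive ", min(ref_res), "..",
           max(ref_res), ")")
    grp <- (seq_len(nrow(d)) - 1L) %/% block
    for (gi in unique(grp)) {
      a <- which(grp == gi)
      w <- d$mass[a] / sum(d$mass[a])
      xs[[length(xs) + 1L]] <- c(sum(w * d$x[a]), sum(w * d$y[a]),
                                 sum(w * d$z[a]))
      sub_id <- c(sub_id, s)
    }
  }
  x <- do.call(rbind, xs)
  cg_system(x, rep("PROT", nrow(x)), mol = sub_id, subunit = sub_id)
}

#' Build a homogeneous elastic network (ENM)
#'
#' Connects every pair of protein beads closer than `cutoff` with a
#' harmonic spring `sc * (r - r0)^2`, `r0` being the build-time distance.
#' The customary spring constants for the seipin model are 0.2 or
#' 2 kcal/mol/A^2 with a 15 A cutoff.
#'
#' @param sys A `cg_system`, or an n x 3 coordinate matrix.
#' @param sc Spring constant in kcal/mol/A^2 (default 0.2).
#' @param cutoff Distance cutoff in nm (default 1.5, i.e. 15 A).
#' @param beads Logical/integer selection of beads to network (default:
#'   protein beads including proteinized PLs).
#' @param exclude_bonded Drop pairs already covered by a bond or spring.
#' @return If `sys` is a `cg_system`, the system with the springs appended;
#'   otherwise the spring data.frame `i, j, k, r0`.
#' @export
build_enm <- function(sys, sc = 0.2, cutoff = 1.5, beads = NULL,
                      exclude_bonded = TRUE) {
  stopifnot(sc > 0, cutoff > 0)
  bare <- !inherits(sys, "cg_system")
  x <- if (bare) as.matrix(sys) else sys$x
  idx <- if (bare) seq_len(nrow(x))
         else if (is.null(beads)) which(is_protein_bead(sys))
         else seq_len(nrow(x))[beads]
  d <- as.matrix(stats::dist(x[idx, , drop = FALSE]))
  pair <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  springs <- data.frame(i = idx[pair[, 1L]], j = idx[pair[, 2L]],
                        k = rep(sc, nrow(pair)), r0 = d[pair])
  if (!bare && exclude_bonded && nrow(springs)) {
    key <- function(d2) paste(pmin(d2$i, d2$j), pmax(d2$i, d2$j))
    taken <- c(key(sys$bonds), key(sys$springs))
    springs <- springs[!(key(springs) %in% taken), , drop = FALSE]
  }
  rownames(springs) <- NULL
  if (bare) return(springs)
  sys$springs <- rbind(sys$springs, springs)
  sys
}

#' Backfill springs between beads not covered by an elastic network
#'
#' Adds weak harmonic springs (default 0.1 kcal/mol/A^2 within 11 A)
#' between protein bead pairs that do not already share a spring or bond,
#' ensuring connections between subunits when a fluctuation-matched network
#' was fitted per monomer.
#'
#' @param sys A `cg_system`.
#' @param sc Spring constant, kcal/mol/A^2 (default 0.1).
#' @param cutoff Distance cutoff, nm (default 1.1, i.e. 11 A).
#' @return The system with the extra springs appended.
#' @export
backfill_springs <- function(sys, sc = 0.1, cutoff = 1.1) {
  cand <- build_enm(sys, sc = sc, cutoff = cutoff, exclude_bonded = TRUE)
  cand
}

#' Place proteinized PL molecules inside the HH ring
#'
#' Adds `n` four-site PL molecules inside the hydrophobic-helix ring,
#' oriented like the lumenal-leaflet lipids (head pointing to the lumen),
#' flags their beads `proteinized_pl` and ties each of them into the
#' protein's elastic network (springs to every protein bead within
#' `spring_cutoff`, plus the nearest protein bead so every molecule is
#' connected).
#'
#' @param sys A `cg_system` holding the protein model, built in the
#'   membrane frame (z = 0 at the bilayer midplane, cytosol at +z).
#' @param n Number of PL molecules (default 24).
#' @param hh_center XY center of the HH ring (nm).
#' @param hh_radius HH ring radius (nm, default 2).
#' @param head_z z of the head bead (nm, default -2.2: lumenal surface).
#' @param bond_k,bond_r0 Lipid bond parameters (kcal/mol/A^2, nm).
#' @param spring_sc,spring_cutoff Elastic-network coupling to the protein.
#' @param clash Minimum allowed distance to existing beads (nm).
#' @param max_retry Jitter retries before failing on a clash.
#' @param seed RNG seed for the jitter.
#' @return The extended `cg_system`.
#' @export
add_proteinized_pls <- function(sys, n = 24L, hh_center = c(0, 0),
                                hh_radius = 2.0, head_z = -2.2,
                                bond_k = 2.5, bond_r0 = 0.5,
                                spring_sc = 0.2, spring_cutoff = 1.2,
                                clash = 0.25, max_retry = 20L, seed = 1L) {
  if (n == 0L) return(sys)
  set.seed(seed)
  ## concentric rings filling the HH ring interior
  per_ring <- c(1L, 7L, 16L)
  radii <- c(0, 0.45, 0.78) * hh_radius
  lateral <- list()
  left <- n
  for (ri in seq_along(per_ring)) {
    m <- min(per_ring[ri], left)
    if (m == 0L) break
    ang <- 2 * pi * seq_len(m) / m
    lateral[[ri]] <- cbind(hh_center[1] + radii[ri] * cos(ang),
                           hh_center[2] + radii[ri] * sin(ang))
    left <- left - m
  }
  if (left > 0L) {  # spill into an extra ring if n > 24
    ang <- 2 * pi * seq_len(left) / left
    lateral[[length(lateral) + 1L]] <-
      cbind(hh_center[1] + 0.92 * hh_radius * cos(ang),
            hh_center[2] + 0.92 * hh_radius * sin(ang))
  }
  lateral <- do.call(rbind, lateral)

  zs <- head_z + bond_r0 * (0:3)  # head deepest; tails point to midplane
  types <- c("PL_head", "PL_int", "PL_tail", "PL_tail")
  prot_x <- sys$x[is_protein_bead(sys), , drop = FALSE]

  xs <- NULL; mol <- integer(0)
  for (m in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      jit <- if (try == 1L) c(0, 0) else runif(2, -0.15, 0.15)
      cand <- cbind(lateral[m, 1] + jit[1], lateral[m, 2] + jit[2], zs)
      dmin <- sqrt(min(pmax(0, outer(rowSums(cand^2), rowSums(prot_x^2), "+") -
                            2 * cand %*% t(prot_x))))
      if (dmin > clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place proteinized PL ", m,
                  " without clashing (", max_retry, " retries)")
    xs <- rbind(xs, cand)
    mol <- c(mol, rep(m, 4L))
  }

  nb <- nrow(xs)
  b0 <- rep(seq(1L, nb, by = 4L), each = 3L) + 0:2
  lip <- cg_system(xs, rep(types, n), mol,
                   flags = list(proteinized_pl = rep(TRUE, nb)),
                   bonds = data.frame(i = b0, j = b0 + 1L,
                                      k = bond_k, r0 = bond_r0),
                   angles = data.frame(
                     i = rep(seq(1L, nb, by = 4L), each = 2L) + 0:1,
                     j = rep(seq(2L, nb, by = 4L), each = 2L) + 0:1,
                     l = rep(seq(3L, nb, by = 4L), each = 2L) + 0:1,
                     k = 0.5 * .kB * 310, theta0 = pi))
  out <- combine_systems(sys, lip)

  ## elastic coupling of every proteinized PL to the protein cage
  prot_idx <- which(out$type == "PROT")
  new_idx <- seq_len(nb) + n_beads(sys)
  sp <- list()
  for (b in new_idx) {
    d <- sqrt(colSums((t(out$x[prot_idx, , drop = FALSE]) - out$x[b, ])^2))
    close <- which(d < spring_cutoff)
    if (length(close) == 0L) close <- which.min(d)
    sp[[length(sp) + 1L]] <- data.frame(i = b, j = prot_idx[close],
                                        k = spring_sc, r0 = d[close])
  }
  out$springs <- rbind(out$springs, do.call(rbind, sp))
  out
}

#' Remove subunits or the TM segments from the seipin oligomer
#'
#' `remove_subunits` deletes `n` ring-contiguous subunits (removing 6 of 11
#' leaves the 5-subunit model); `lumenal_only` deletes every bead flagged
#' as part of a TM segment, leaving only the lumenal domain.  Elastic
#' springs incident to removed beads are deleted with them.
#'
#' @param sys A `cg_system` with subunit annotations.
#' @param mode `"remove_subunits"` or `"lumenal_only"`.
#' @param n Number of contiguous subunits to remove.
#' @param start First subunit to remove (ring position).
#' @return The truncated `cg_system`.
#' @export
truncate_oligomer <- function(sys, mode = c("remove_subunits", "lumenal_only"),
                              n = 6L, start = 1L) {
  mode <- match.arg(mode)
  if (mode == "lumenal_only")
    return(subset_beads(sys, !sys$flags$tm_segment))
  if (n == 0L) return(sys)
  subs <- sort(unique(sys$subunit[!is.na(sys$subunit)]))
  if (n >= length(subs))
    stop("cannot remove ", n, " of ", length(subs), " subunits")
  drop <- subs[((start - 1L + seq_len(n) - 1L) %% length(subs)) + 1L]
  subset_beads(sys, is.na(sys$subunit) | !(sys$subunit %in% drop))
}

#' Attraction scaling-factor table
#'
#' Scaling factors multiply the depth and force of the attractive part of
#' the pair potential linearly.  Defaults follow the CG seipin model:
#' protein beads in the hydrophobic phase attract PL tails with factor 1
#' (equal to the lipid-lipid attraction); protein beads at the membrane
#' interface attract PL interfacial beads with factor 1.5; the two HH beads
#' and the four central beads of each TM segment attract TG (glycerol and
#' tail) with factor 1.5; the TM terminal tips attract PL interfacial and
#' head beads with factor `tip_scaling` (the `r` knob of the
#' scaling-factor experiments).  Lipid-lipid defaults: tails (PL and TG)
#' and the TG glycerol attract one another and interfacial beads attract
#' interfacial beads, all with factor 1; everything else is purely
#' repulsive (factor 0).
#'
#' @param overrides Named list `"classA|classB" = factor` applied last;
#'   class names as in [interaction_classes()].
#' @param tip_scaling Scaling factor of the TM tip / membrane-interface
#'   attraction (default 1.5).
#' @return Symmetric numeric matrix (class `interaction_table`) over the
#'   interaction classes.
#' @export
#' @examples
#' tab <- build_interaction_table()
#' tab["P_interface", "PL_int"]  # 1.5
build_interaction_table <- function(overrides = NULL, tip_scaling = 1.5) {
  cls <- interaction_classes()
  tab <- matrix(0, length(cls), length(cls), dimnames = list(cls, cls))
  set <- function(a, b, f) {
    tab[a, b] <<- f
    tab[b, a] <<- f
  }
  ## lipid-lipid: hydrophobic beads cohere; interfacial beads cohere
  hydro <- c("PL_tail", "TG_tail", "TG_gly")
  for (a in hydro) for (b in hydro) set(a, b, 1)
  set("PL_int", "PL_int", 1)
  ## protein-lipid
  phobic_prot <- c("P_phobic", "P_tg_tm", "P_tg_hh")
  for (a in phobic_prot) set(a, "PL_tail", 1)
  set("P_interface", "PL_int", 1.5)
  set("P_tip", "PL_int", tip_scaling)
  set("P_tip", "PL_head", tip_scaling)
  for (a in c("P_tg_tm", "P_tg_hh")) {
    set(a, "TG_tail", 1.5)
    set(a, "TG_gly", 1.5)
  }
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      ab <- strsplit(nm, "|", fixed = TRUE)[[1L]]
      if (length(ab) != 2L || !all(ab %in% cls))
        stop("unknown interaction pair '", nm, "'")
      if (overrides[[nm]] < 0) stop("negative scaling factor for '", nm, "'")
      set(ab[1L], ab[2L], overrides[[nm]])
    }
  }
  structure(tab, class = c("interaction_table", "matrix"))
}

#' Build a spherical CG bilayer
#'
#' Two concentric spherical leaflets of linear four-site PLs (heads
#' outermost / innermost, tails facing the midplane), with TG molecules
#' placed uniformly at random in the tail region at the requested mol%
#' (TG / (TG + PL)).  Heads are laid out on near-uniform Fibonacci
#' lattices; counts per leaflet are proportional to leaflet head areas.
#'
#' @param diameter Outer diameter in nm (40 or 60 in the production runs).
#' @param tg_percent TG mol% (2 or 6 in the production runs).
#' @param apl Area per lipid, nm^2 (default 0.7).
#' @param thickness Head-to-head bilayer thickness, nm (default 3.5).
#' @param spacing Intramolecular bead spacing, nm (default 0.5).
#' @param bond_k Lipid bond constant, kcal/mol/A^2.
#' @param angle_k PL angle constant, kcal/mol/rad^2 (default 0.5 kB T at
#'   310 K; TG carries no angle terms).
#' @param box_margin Box padding beyond the vesicle, nm.
#' @param seed RNG seed.
#' @return A `cg_system` in a cubic periodic box.
#' @export
build_spherical_bilayer <- function(diameter = 40, tg_percent = 2,
                                    apl = 0.7, thickness = 3.5,
                                    spacing = 0.5, bond_k = 2.5,
                                    angle_k = 0.5 * .kB * 310,
                                    box_margin = 10, seed = 1L) {
  stopifnot(diameter > 0, tg_percent >= 0, tg_percent < 100)
  set.seed(seed)
  R <- diameter / 2
  r_out <- R; r_in <- R - thickness
  if (r_in <= 4 * spacing) stop("vesicle too small for the bilayer thickness")
  n_out <- round(4 * pi * r_out^2 / apl)
  n_in <- round(4 * pi * r_in^2 / apl)

  fib <- function(n) {  # Fibonacci sphere directions
    i <- seq_len(n) - 0.5
    phi <- pi * (1 + sqrt(5)) * i
    z <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(r * cos(phi), r * sin(phi), z)
  }

  place_leaflet <- function(n, r_head, inward) {
    u <- fib(n)
    radii <- if (inward) r_head + spacing * (0:3) else r_head - spacing * (0:3)
    x <- matrix(0, 4L * n, 3L)
    for (m in seq_len(n))
      x[(m - 1L) * 4L + 1:4, ] <- radii %o% u[m, ]  # 4 beads along the normal
    x
  }
  x_out <- place_leaflet(n_out, r_out, inward = FALSE)
  x_in <- place_leaflet(n_in, r_in, inward = TRUE)

  n_pl <- n_out + n_in
  xs <- rbind(x_out, x_in)
  types <- rep(c("PL_head", "PL_int", "PL_tail", "PL_tail"), n_pl)
  mol <- rep(seq_len(n_pl), each = 4L)

  ## TG in the tail shell
  n_tg <- round(n_pl * tg_percent / (100 - tg_percent))
  if (n_tg > 0L) {
    r_mid <- (r_out + r_in) / 2
    u <- fib(n_tg)
    u <- u[sample.int(n_tg), , drop = FALSE]  # decorrelate from PL lattice
    for (m in seq_len(n_tg)) {
      base <- u[m, ] * (r_mid + runif(1, -0.4, 0.4))
      t1 <- .tangent_basis(u[m, ])
      pos <- rbind(base,
                   base + 0.45 * t1$a,
                   base - 0.45 * t1$a,
                   base + 0.45 * t1$b)
      xs <- rbind(xs, pos)
      types <- c(types, c("TG_gly", rep("TG_tail", 3L)))
      mol <- c(mol, rep(n_pl + m, 4L))
    }
  }

  ## drop PL molecules overlapping a TG bead (startable configuration)
  if (n_tg > 0L) {
    tg_rows <- which(mol > n_pl)
    txs <- t(xs[tg_rows, , drop = FALSE])
    bad <- logical(n_pl)
    for (m in seq_len(n_pl)) {
      rows <- 4L * (m - 1L) + 1:4
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
      n_pl <- n_pl - sum(bad)
    }
  }

  nb <- nrow(xs)
  first <- seq(1L, nb, by = 4L)
  pl_first <- first[seq_len(n_pl)]
  bonds <- rbind(
    data.frame(i = rep(pl_first, each = 3L) + 0:2,
               j = rep(pl_first, each = 3L) + 1:3,
               k = bond_k, r0 = spacing),
    if (n_tg > 0L) {
      tg_first <- first[n_pl + seq_len(n_tg)]
      ## star topology: glycerol bonded to the three tails
      data.frame(i = rep(tg_first, each = 3L),
                 j = rep(tg_first, each = 3L) + 1:3,
                 k = bond_k, r0 = 0.45)
    })
  angles <- data.frame(i = rep(pl_first, each = 2L) + 0:1,
                       j = rep(pl_first, each = 2L) + 1:2,
                       l = rep(pl_first, each = 2L) + 2:3,
                       k = angle_k, theta0 = pi)
  box <- rep(diameter + 2 * box_margin, 3L)
  xs <- xs + matrix(box / 2, nb, 3L, byrow = TRUE)  # center in the box
  cg_system(xs, types, mol, bonds = bonds, angles = angles, box = box)
}

#' Embed a protein model into a flat bilayer patch
#'
#' Places a protein built in the membrane frame (z = 0 at the midplane) at
#' the lateral center of a flat patch (see [gen_bilayer_patch()]) and
#' removes lipid molecules with any bead within `clash` of any protein
#' bead.
#'
#' @param patch A `cg_system` flat patch.
#' @param protein A `cg_system` protein model in the membrane frame.
#' @param clash Removal cutoff, nm (default 0.5).
#' @return The combined `cg_system`.
#' @export
embed_protein_patch <- function(patch, protein, clash = 0.5) {
  box <- patch$box
  prot <- protein
  prot$x <- sweep(prot$x, 2L, c(box[1L] / 2, box[2L] / 2, box[3L] / 2), "+")
  d2min <- rep(Inf, n_beads(patch))
  rmax <- max(sqrt((prot$x[, 1L] - box[1L] / 2)^2 +
                   (prot$x[, 2L] - box[2L] / 2)^2)) + clash + 0.5
  near <- which(sqrt((patch$x[, 1L] - box[1L] / 2)^2 +
                     (patch$x[, 2L] - box[2L] / 2)^2) < rmax)
  px <- t(prot$x)
  for (b in near) d2min[b] <- min(colSums((px - patch$x[b, ])^2))
  bad_mol <- unique(patch$mol[d2min < clash^2])
  combine_systems(subset_beads(patch, !(patch$mol %in% bad_mol)), prot)
}

.tangent_basis <- function(u) {
  ref <- if (abs(u[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  a <- ref - sum(ref * u) * u
  a <- a / sqrt(sum(a^2))
  b <- c(u[2L] * a[3L] - u[3L] * a[2L],
         u[3L] * a[1L] - u[1L] * a[3L],
         u[1L] * a[2L] - u[2L] * a[1L])
  list(a = a, b = b)
}

#' Embed a protein model into a spherical bilayer
#'
#' The protein, built in the flat-membrane frame (z = 0 at the midplane,
#' cytosol at +z), is placed at the vesicle's north pole with the cytosolic
#' side facing outward and the lumenal domain pointing into the vesicle
#' interior.  Lipid molecules with any bead within `clash` of any protein
#' bead are removed whole.
#'
#' @param bilayer A `cg_system` from [build_spherical_bilayer()].
#' @param protein A `cg_system` protein model in the membrane frame.
#' @param clash Removal cutoff in nm (default 0.5).
#' @param thickness Bilayer head-to-head thickness used to locate the
#'   midplane radius (must match the bilayer build).
#' @return The combined `cg_system`.
#' @export
embed_protein <- function(bilayer, protein, clash = 0.5, thickness = 3.5) {
  box <- bilayer$box
  ctr <- box / 2
  lip_r <- sqrt(rowSums((bilayer$x - matrix(ctr, n_beads(bilayer), 3L,
                                            byrow = TRUE))^2))
  r_out <- max(lip_r)
  r_mid <- r_out - thickness / 2
  prot <- protein
  if (max(abs(prot$x[, 1:2])) > r_mid)
    stop("protein wider than the vesicle midplane radius")
  prot$x <- cbind(prot$x[, 1L] + ctr[1L], prot$x[, 2L] + ctr[2L],
                  prot$x[, 3L] + ctr[3L] + r_mid)

  ## drop whole lipid molecules clashing with the protein
  d2min <- rep(Inf, n_beads(bilayer))
  near <- which(bilayer$x[, 3L] > ctr[3L] + r_mid - thickness - 2 &
                sqrt((bilayer$x[, 1L] - ctr[1L])^2 +
                     (bilayer$x[, 2L] - ctr[2L])^2) <
                  max(abs(prot$x[, 1L] - ctr[1L])) + 2 * clash + 2)
  if (length(near)) {
    px <- prot$x
    for (b in near)
      d2min[b] <- min(colSums((t(px) - bilayer$x[b, ])^2))
  }
  bad_mol <- unique(bilayer$mol[d2min < clash^2])
  kept <- subset_beads(bilayer, !(bilayer$mol %in% bad_mol))
  combine_systems(kept, prot)
}
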