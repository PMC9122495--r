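## Fixtures and independent oracles shared across the test files.

## atomistic molecules built from the shipped scheme atom tables
make_molecule_atoms <- function(kind, mol_id = 1L, center = c(0, 0, 0),
                                spread = 0.3, seed = 1L) {
  sch <- build_default_schemes()[[kind]]
  nm <- unlist(sch$groups$atoms)
  set.seed(seed + mol_id)
  data.frame(name = nm, kind = if (kind == "residue") "residue" else kind,
             mol_id = mol_id,
             x = center[1] + rnorm(length(nm), 0, spread),
             y = center[2] + rnorm(length(nm), 0, spread),
             z = center[3] + rnorm(length(nm), 0, spread))
}

make_residue_atoms <- function(mol_id = 1L, center = c(0, 0, 0), seed = 1L) {
  set.seed(seed + mol_id)
  nm <- c("N", "CA", "C", "O", "CB", "CG", "CD")  # backbone + sidechain
  data.frame(name = nm, kind = "residue", mol_id = mol_id,
             x = center[1] + rnorm(7, 0, 0.1),
             y = center[2] + rnorm(7, 0, 0.1),
             z = center[3] + rnorm(7, 0, 0.1))
}

## a small grouped frame with lipid groups at given positions
make_lipid_frame <- function(pl_xyz = NULL, tg_xyz = NULL,
                             tg_kind = NULL, box = c(10, 10, 10)) {
  ent <- list()
  if (!is.null(pl_xyz))
    for (m in seq_len(nrow(pl_xyz)))
      ent[[length(ent) + 1L]] <- data.frame(
        mol_id = 100L + m, mol_kind = "PL", label = "GL",
        group_kind = "glycerol", x = pl_xyz[m, 1], y = pl_xyz[m, 2],
        z = pl_xyz[m, 3], n_atoms = 9L, mass = 100)
  if (!is.null(tg_xyz)) {
    if (is.null(tg_kind)) tg_kind <- rep("tail", nrow(tg_xyz))
    for (m in seq_len(nrow(tg_xyz)))
      ent[[length(ent) + 1L]] <- data.frame(
        mol_id = 200L + m, mol_kind = "TG", label = "T",
        group_kind = tg_kind[m], x = tg_xyz[m, 1], y = tg_xyz[m, 2],
        z = tg_xyz[m, 3], n_atoms = 4L, mass = 55)
  }
  d <- do.call(rbind, ent)
  attr(d, "box") <- box
  class(d) <- c("grouped_frame", "data.frame")
  d
}

## independent brute-force coordination oracle: plain double loop
oracle_coordination <- function(probe, targets, r0, box) {
  s <- 0
  for (t in seq_len(nrow(targets))) {
    d <- targets[t, ] - probe
    d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    x6 <- (r / r0)^6
    s <- s + if (abs(x6 - 1) < 1e-12) 0.5 else (1 - x6) / (1 - x6 * x6)
  }
  s
}

## independent union-find single-linkage clustering oracle
oracle_cluster <- function(x, mol, cutoff, box = NULL) {
  mols <- unique(mol)
  parent <- seq_along(mols)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  for (p in seq_len(nrow(x) - 1L)) for (q in (p + 1L):nrow(x)) {
    if (mol[p] == mol[q]) next
    d <- x[p, ] - x[q, ]
    if (!is.null(box)) d <- d - box * round(d / box)
    if (sqrt(sum(d^2)) < cutoff) {
      a <- find(match(mol[p], mols)); b <- find(match(mol[q], mols))
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_along(mols), find, 0L)
  match(roots, unique(roots))
}

## 20-bead planar grid elastic network whose spring set is identifiable
## (all spring lengths well below, all non-springs well above, the cutoff)
grid_network <- function(k = 0.5, spacing = 0.9, jitter = 0.03,
                         cutoff = 1.1, seed = 42L) {
  set.seed(seed)
  g <- expand.grid(x = 0:3, y = 0:4) * spacing
  x <- cbind(g$x, g$y, 0) + matrix(rnorm(60, 0, jitter), 20, 3)
  list(x = x, springs = build_enm(x, sc = k, cutoff = cutoff),
       cutoff = cutoff)
}

## 50-bead lattice system with all interaction terms, free of bad contacts
lattice_system <- function(n = 50L, seed = 5L) {
  set.seed(seed)
  g <- expand.grid(x = 1:4, y = 1:4, z = 1:4)[seq_len(n), ] * 0.8
  x <- as.matrix(g) + matrix(runif(3 * n, -0.15, 0.15), n, 3)
  types <- sample(c("PL_head", "PL_int", "PL_tail", "TG_gly", "TG_tail"),
                  n, TRUE)
  cg_system(x, types, seq_len(n),
            bonds = data.frame(i = 1:10, j = 11:20, k = 2.5, r0 = 0.5),
            angles = data.frame(i = 1:5, j = 21:25, l = 31:35,
                                k = 0.3, theta0 = 2.0),
            springs = data.frame(i = 41:45, j = 46:50, k = 0.2, r0 = 0.8),
            box = c(20, 20, 20))
}
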