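## The CG system container: beads, bonds, angles, elastic springs.
##
## Coordinates are in nm; spring/bond constants are stored in kcal/mol/A^2
## (the unit customary for these models) with equilibrium lengths in nm;
## the bond energy convention is k * (r - r0)^2, without a 1/2 prefactor.

.bead_types <- c("PL_head", "PL_int", "PL_tail", "TG_gly", "TG_tail", "PROT")
.flag_names <- c("hydrophobic_phase", "interfacial", "tg_attract_hh",
                 "tg_attract_tm", "tm_tip", "tm_segment", "proteinized_pl")

.empty_bonds <- function()
  data.frame(i = integer(0), j = integer(0), k = numeric(0), r0 = numeric(0))
.empty_angles <- function()
  data.frame(i = integer(0), j = integer(0), l = integer(0),
             k = numeric(0), theta0 = numeric(0))

#' Construct a CG system
#'
#' @param x n x 3 coordinate matrix (nm).
#' @param type Character vector of bead types (`PL_head`, `PL_int`,
#'   `PL_tail`, `TG_gly`, `TG_tail`, `PROT`).
#' @param mol Integer molecule id per bead.
#' @param subunit Integer subunit id per bead (NA for lipids).
#' @param flags Named list of logical vectors (annotation flags); missing
#'   flags are filled with FALSE.
#' @param bonds,springs data.frame `i, j, k, r0` (k in kcal/mol/A^2, r0 in
#'   nm, energy `k (r - r0)^2`).
#' @param angles data.frame `i, j, l, k, theta0` (j is the apex; k in
#'   kcal/mol/rad^2, theta0 in radians, energy `k (theta - theta0)^2`).
#' @param box Length-3 periodic box (nm) or NULL.
#' @return Object of class `cg_system`.  Every bead carries a mass of
#'   200 g/mol and no charge.
#' @export
cg_system <- function(x, type, mol, subunit = NULL, flags = list(),
                      bonds = .empty_bonds(), angles = .empty_angles(),
                      springs = .empty_bonds(), box = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(ncol(x) == 3L, length(type) == n, length(mol) == n,
            all(type %in% .bead_types))
  if (is.null(subunit)) subunit <- rep(NA_integer_, n)
  fl <- lapply(setNames(.flag_names, .flag_names), function(f)
    if (is.null(flags[[f]])) rep(FALSE, n) else flags[[f]])
  stopifnot(all(vapply(fl, length, 0L) == n))
  for (d in list(bonds, springs))
    if (nrow(d) && (any(d$k <= 0) | any(d$i == d$j)))
      stop("bond/spring constants must be positive and i != j")
  structure(list(x = x, type = type, mol = as.integer(mol),
                 subunit = as.integer(subunit),
                 mass = rep(200, n), charge = rep(0, n), flags = fl,
                 bonds = bonds, angles = angles, springs = springs,
                 box = box),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat("cg_system:", nrow(x$x), "beads,", length(unique(x$mol)), "molecules,",
      nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$springs), "springs\n")
  cat("  types:", paste(names(table(x$type)), table(x$type),
                        sep = ":", collapse = "  "), "\n")
  if (!is.null(x$box))
    cat("  box:", paste(signif(x$box, 4), collapse = " x "), "nm\n")
  invisible(x)
}

#' Number of beads in a CG system
#' @param sys A `cg_system`.
#' @export
n_beads <- function(sys) nrow(sys$x)

#' Protein beads (including proteinized PLs)
#' @param sys A `cg_system`.
#' @return Logical vector: beads that belong to the protein model, i.e.
#'   `PROT` beads and PL beads flagged `proteinized_pl`.
#' @export
is_protein_bead <- function(sys)
  sys$type == "PROT" | sys$flags$proteinized_pl

#' Keep a subset of beads, reindexing all topology tables
#'
#' Bonds, angles and springs with any removed endpoint are deleted.
#'
#' @param sys A `cg_system`.
#' @param keep Logical or integer index of beads to keep.
#' @return The filtered `cg_system`.
#' @export
subset_beads <- function(sys, keep) {
  keep <- seq_len(n_beads(sys))[keep]
  newid <- rep(NA_integer_, n_beads(sys))
  newid[keep] <- seq_along(keep)
  remap2 <- function(d) {
    d <- d[d$i %in% keep & d$j %in% keep, , drop = FALSE]
    d$i <- newid[d$i]; d$j <- newid[d$j]
    rownames(d) <- NULL; d
  }
  ang <- sys$angles
  ang <- ang[ang$i %in% keep & ang$j %in% keep & ang$l %in% keep, , drop = FALSE]
  ang$i <- newid[ang$i]; ang$j <- newid[ang$j]; ang$l <- newid[ang$l]
  rownames(ang) <- NULL
  cg_system(sys$x[keep, , drop = FALSE], sys$type[keep], sys$mol[keep],
            sys$subunit[keep], lapply(sys$flags, `[`, keep),
            remap2(sys$bonds), ang, remap2(sys$springs), sys$box)
}

#' Combine two CG systems
#'
#' Bead, molecule and topology indices of `b` are shifted past those of
#' `a`; the box of `a` is kept.
#'
#' @param a,b `cg_system` objects.
#' @export
combine_systems <- function(a, b) {
  off <- n_beads(a)
  moff <- if (length(a$mol)) max(a$mol) else 0L
  shift2 <- function(d) { d$i <- d$i + off; d$j <- d$j + off; d }
  ang <- b$angles
  if (nrow(ang)) { ang$i <- ang$i + off; ang$j <- ang$j + off; ang$l <- ang$l + off }
  soff <- max(c(0L, a$subunit), na.rm = TRUE)
  cg_system(rbind(a$x, b$x), c(a$type, b$type), c(a$mol, b$mol + moff),
            c(a$subunit, b$subunit + soff),
            lapply(setNames(.flag_names, .flag_names), function(f)
              c(a$flags[[f]], b$flags[[f]])),
            rbind(a$bonds, shift2(b$bonds)), rbind(a$angles, ang),
            rbind(a$springs, shift2(b$springs)), a$box)
}

#' Fine-grained interaction classes of the beads
#'
#' Resolves each bead's type and annotation flags into one of the
#' interaction classes used by [build_interaction_table()] and the engine:
#' `PL_head`, `PL_int`, `PL_tail`, `TG_gly`, `TG_tail`, `P_other`,
#' `P_phobic`, `P_interface`, `P_tg_tm`, `P_tg_hh`, `P_tip`.
#'
#' @param sys A `cg_system`.
#' @return Factor of interaction classes (levels in table order).
#' @export
bead_class <- function(sys) {
  cls <- sys$type
  p <- sys$type == "PROT"
  cls[p] <- "P_other"
  cls[p & sys$flags$hydrophobic_phase] <- "P_phobic"
  cls[p & sys$flags$interfacial] <- "P_interface"
  cls[p & sys$flags$tg_attract_tm] <- "P_tg_tm"
  cls[p & sys$flags$tg_attract_hh] <- "P_tg_hh"
  cls[p & sys$flags$tm_tip] <- "P_tip"
  factor(cls, levels = interaction_classes())
}

#' @rdname bead_class
#' @export
interaction_classes <- function()
  c("PL_head", "PL_int", "PL_tail", "TG_gly", "TG_tail",
    "P_other", "P_phobic", "P_interface", "P_tg_tm", "P_tg_hh", "P_tip")
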