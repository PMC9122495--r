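## Per-residue coordination-number statistic against PL and TG groups.
##
## The statistic sums, over target groups, the rational switching function
## [1 - (r/r0)^6] / [1 - (r/r0)^12], evaluated in the algebraically
## equivalent singularity-free form 1 / (1 + (r/r0)^6).

#' Switching-function parameters
#'
#' @param r0 Switching radius in nm (default 0.4).
#' @return Object of class `switching_params`.
#' @export
switching_params <- function(r0 = 0.4) {
  stopifnot(is.numeric(r0), length(r0) == 1L, r0 > 0)
  structure(list(r0 = r0), class = "switching_params")
}

#' Rational switching function for coordination numbers
#'
#' Evaluates `[1 - (r/r0)^6] / [1 - (r/r0)^12]` through the equivalent,
#' singularity-free form `1 / (1 + (r/r0)^6)`.  Strictly decreasing in r,
#' equal to 1 at r = 0 and to 1/2 at r = r0.
#'
#' @param r Distances in nm (vectorized, must be >= 0).
#' @param params A [switching_params()] object.
#' @return Values in (0, 1].
#' @export
#' @examples
#' switching_value(c(0, 0.4, 0.8))  # 1, 0.5, 1/65
switching_value <- function(r, params = switching_params()) {
  if (any(r < 0)) stop("negative distance passed to switching_value")
  1 / (1 + (r / params$r0)^6)
}

## minimum-image displacement components for an orthorhombic periodic box
.min_image <- function(d, box) d - box * round(d / box)

.target_rows <- function(frame, target_kind) {
  switch(target_kind,
    "PL" = which(frame$mol_kind == "PL"),
    "TG" = which(frame$mol_kind == "TG"),
    "TG-glycerol" = which(frame$mol_kind == "TG" &
                          frame$group_kind == "glycerol"),
    "TG-tail" = which(frame$mol_kind == "TG" & frame$group_kind == "tail"),
    stop("unknown target kind '", target_kind, "'")
  )
}

#' Coordination number of a probe group with membrane groups
#'
#' Sums the switching function over all target lipid groups, with
#' minimum-image distances under the frame's periodic box.
#'
#' @param probe Length-3 numeric, probe group position (nm) -- typically a
#'   residue side-chain group.
#' @param frame A `grouped_frame` (see [map_frame()]).
#' @param target_kind One of `"PL"`, `"TG"`, `"TG-glycerol"`, `"TG-tail"`.
#' @param params A [switching_params()] object.
#' @return Unitless coordination number (>= 0).
#' @export
coordination_number <- function(probe, frame, target_kind = "PL",
                                params = switching_params()) {
  rows <- .target_rows(frame, target_kind)
  if (length(rows) == 0L)
    stop("empty target selection '", target_kind, "' in frame")
  box <- attr(frame, "box")
  dx <- .min_image(frame$x[rows] - probe[1], box[1])
  dy <- .min_image(frame$y[rows] - probe[2], box[2])
  dz <- .min_image(frame$z[rows] - probe[3], box[3])
  sum(switching_value(sqrt(dx^2 + dy^2 + dz^2), params))
}

#' Normalize a coordination number
#'
#' Per-molecule normalization divides by the number of molecules of the
#' target species; per-atom normalization divides by the number of grouped
#' atoms of the selected part (e.g. 12 tail groups or 1 glycerol group per
#' TG molecule).
#'
#' @param s Coordination number(s).
#' @param denom Positive count.
#' @param mode `"per_molecule"` or `"per_atom"` (recorded as an attribute).
#' @return `s / denom`.
#' @export
normalize_coordination <- function(s, denom,
                                   mode = c("per_molecule", "per_atom")) {
  mode <- match.arg(mode)
  if (length(denom) != 1L || denom == 0)
    stop("normalization denominator must be a single nonzero count")
  structure(s / denom, mode = mode)
}

#' Per-residue coordination profiles with block errors
#'
#' For every protein side-chain group, computes time-averaged coordination
#' numbers with PL and TG, the per-molecule normalized values, and the
#' per-atom normalized values for the TG glycerol and tail sub-parts.
#' Frames are split into `n_blocks` equal-length blocks; the reported value
#' is the mean over block means and the error the standard error across
#' blocks.
#'
#' @param frames List of `grouped_frame` objects.
#' @param params A [switching_params()] object.
#' @param n_blocks Number of blocks for error estimation (default 3).
#' @return data.frame with one row per residue: `residue`, `s_PL`, `s_TG`,
#'   per-molecule columns (`s_PL_per_mol`, `s_TG_per_mol`), per-atom
#'   columns (`s_TG_gly_per_atom`, `s_TG_tail_per_atom`) and `_se`
#'   companions.
#' @export
residue_profile <- function(frames, params = switching_params(),
                            n_blocks = 3L) {
  stopifnot(length(frames) >= n_blocks)
  n_use <- (length(frames) %/% n_blocks) * n_blocks
  if (n_use < length(frames))
    warning("dropping ", length(frames) - n_use,
            " trailing frame(s) not divisible into ", n_blocks, " blocks")
  blocks <- split(seq_len(n_use), rep(seq_len(n_blocks), each = n_use / n_blocks))

  f1 <- frames[[1L]]
  probes <- which(f1$mol_kind == "protein" & f1$group_kind == "sidechain")
  if (length(probes) == 0L) stop("no protein side-chain groups in frames")
  residues <- f1$mol_id[probes]
  n_pl <- length(unique(f1$mol_id[f1$mol_kind == "PL"]))
  n_tg <- length(unique(f1$mol_id[f1$mol_kind == "TG"]))
  n_tg_gly <- sum(f1$mol_kind == "TG" & f1$group_kind == "glycerol")
  n_tg_tail <- sum(f1$mol_kind == "TG" & f1$group_kind == "tail")

  kinds <- c("PL", "TG", "TG-glycerol", "TG-tail")
  ## block means: residues x kinds x blocks
  bm <- array(NA_real_, c(length(residues), length(kinds), n_blocks))
  for (b in seq_len(n_blocks)) {
    acc <- matrix(0, length(residues), length(kinds))
    for (fi in blocks[[b]]) {
      fr <- frames[[fi]]
      pr <- which(fr$mol_kind == "protein" & fr$group_kind == "sidechain")
      pr <- pr[match(residues, fr$mol_id[pr])]
      for (k in seq_along(kinds)) {
        if (length(.target_rows(fr, kinds[k])) == 0L) {
          acc[, k] <- NA_real_
          next
        }
        acc[, k] <- acc[, k] + vapply(pr, function(i)
          coordination_number(c(fr$x[i], fr$y[i], fr$z[i]), fr,
                              kinds[k], params), 0)
      }
    }
    bm[, , b] <- acc / length(blocks[[b]])
  }

  blk_stat <- function(k) {  # residues x blocks -> mean, se
    m <- matrix(bm[, k, ], nrow = length(residues), ncol = n_blocks)
    list(mu = rowMeans(m), se = apply(m, 1L, sd) / sqrt(n_blocks))
  }
  s_pl <- blk_stat(1L)
  s_tg <- blk_stat(2L)
  s_gly <- blk_stat(3L)
  s_tail <- blk_stat(4L)

  data.frame(
    residue = residues,
    s_PL = s_pl$mu, s_PL_se = s_pl$se,
    s_TG = s_tg$mu, s_TG_se = s_tg$se,
    s_PL_per_mol = s_pl$mu / n_pl, s_PL_per_mol_se = s_pl$se / n_pl,
    s_TG_per_mol = s_tg$mu / n_tg, s_TG_per_mol_se = s_tg$se / n_tg,
    s_TG_gly_per_atom = s_gly$mu / n_tg_gly,
    s_TG_gly_per_atom_se = s_gly$se / n_tg_gly,
    s_TG_tail_per_atom = s_tail$mu / n_tg_tail,
    s_TG_tail_per_atom_se = s_tail$se / n_tg_tail
  )
}
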