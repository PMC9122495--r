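## Reduced-resolution grouping of atomistic membrane molecules.
##
## POPC is mapped to 11 molecular groups (choline head, phosphate, glycerol
## moiety, 4 tail groups per acyl chain), TG (triolein) to 13 groups
## (glycerol moiety + 4 tail groups per each of 3 acyl chains) and each
## protein residue to a backbone and a side-chain group.

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06)

#' Guess atomic masses from atom names
#'
#' The element is taken as the first alphabetic character of the atom name
#' (PDB-style naming: `C12`, `O21`, `P`, `HA`...).
#'
#' @param names Character vector of atom names.
#' @return Numeric vector of masses in g/mol.
#' @export
atom_masses <- function(names) {
  el <- sub("^[0-9]*([A-Za-z]).*$", "\\1", names)
  el <- toupper(el)
  m <- .element_masses[el]
  if (anyNA(m))
    stop("cannot assign a mass to atom name(s): ",
         paste(unique(names[is.na(m)]), collapse = ", "))
  unname(m)
}

## contiguous split of chain carbons into 4 blocks, extra carbons going to
## the terminal-most blocks
.chain_blocks <- function(carbons) {
  n <- length(carbons)
  base <- n %/% 4L
  extra <- n %% 4L
  sizes <- rep(base, 4L)
  if (extra > 0L)  # terminal-most blocks receive the extra carbons
    sizes[seq(4L, by = -1L, length.out = extra)] <- base + 1L
  split(carbons, rep(seq_len(4L), sizes))
}

#' Default reduced-resolution grouping schemes
#'
#' Builds the shipped grouping tables: POPC into 11 molecular groups
#' (1 choline head + 1 phosphate + 1 glycerol moiety + 4 tail groups per
#' acyl chain), TG into 13 groups (1 glycerol moiety + 4 tail groups per
#' each of the 3 oleoyl chains, i.e. 12 tail + 1 glycerol) and a protein
#' residue into backbone and side-chain groups.
#'
#' Atom names follow the CHARMM36 heavy-atom convention for POPC
#' (`N, C11..C15`, `P, O11..O14`, glycerol `C1 C2 C3` with ester atoms,
#' sn-1 chain `C32..C316`, sn-2 chain `C22..C218`); triolein uses glycerol
#' `C1 C2 C3` plus three ester triplets and chains `C12..C118`,
#' `C22..C218`, `C32..C318`.  Ester/carbonyl atoms are assigned to the
#' glycerol moiety so that the hydrophilic unit stays intact.  Chain carbons
#' are divided into four contiguous blocks as evenly as possible with extra
#' carbons going to the terminal-most blocks.  Hydrogens are not listed:
#' [map_frame()] attaches them to the group of their nearest heavy atom.
#'
#' @return Named list of `grouping_scheme` objects (`POPC`, `TG`,
#'   `residue`), each a list with `molecule_kind` and `groups`
#'   (data.frame: `label`, `kind`, and a list-column `atoms`).
#' @export
#' @examples
#' sch <- build_default_schemes()
#' nrow(sch$POPC$groups)  # 11
#' table(sch$TG$groups$kind)  # 12 tail + 1 glycerol
build_default_schemes <- function() {
  g <- function(label, kind, atoms)
    list(label = label, kind = kind, atoms = atoms)

  popc_groups <- c(
    list(
      g("NC3", "head", c("N", "C11", "C12", "C13", "C14", "C15")),
      g("PO4", "phosphate", c("P", "O11", "O12", "O13", "O14")),
      g("GL", "glycerol",
        c("C1", "C2", "C3", "O21", "C21", "O22", "O31", "C31", "O32"))
    ),
    ## sn-1 palmitoyl: 15 chain carbons C32..C316
    local({
      blocks <- .chain_blocks(paste0("C3", 2:16))
      lapply(seq_along(blocks), function(i)
        g(paste0("C", i, "A"), "tail", blocks[[i]]))
    }),
    ## sn-2 oleoyl: 17 chain carbons C22..C218
    local({
      blocks <- .chain_blocks(paste0("C2", 2:18))
      lapply(seq_along(blocks), function(i)
        g(paste0("C", i, "B"), "tail", blocks[[i]]))
    })
  )

  tg_groups <- c(
    list(g("GL", "glycerol",
           c("C1", "C2", "C3",
             "O11", "C11", "O12", "O21", "C21", "O22", "O31", "C31", "O32"))),
    unlist(lapply(1:3, function(ch) {
      blocks <- .chain_blocks(paste0("C", ch, 2:18))
      lapply(seq_along(blocks), function(i)
        g(paste0("C", i, LETTERS[ch]), "tail", blocks[[i]]))
    }), recursive = FALSE)
  )

  res_groups <- list(
    g("BB", "backbone", c("N", "CA", "C", "O", "OXT")),
    g("SC", "sidechain", character(0))  # complement of the backbone set
  )

  as_scheme <- function(kind, groups) {
    out <- list(
      molecule_kind = kind,
      groups = data.frame(
        label = vapply(groups, `[[`, "", "label"),
        kind = vapply(groups, `[[`, "", "kind"),
        stringsAsFactors = FALSE
      )
    )
    out$groups$atoms <- lapply(groups, `[[`, "atoms")
    class(out) <- "grouping_scheme"
    out
  }

  list(POPC = as_scheme("POPC", popc_groups),
       TG = as_scheme("TG", tg_groups),
       residue = as_scheme("residue", res_groups))
}

.new_grouped_frame <- function(entries, box) {
  rownames(entries) <- NULL
  attr(entries, "box") <- box
  class(entries) <- c("grouped_frame", "data.frame")
  entries
}

#' @export
print.grouped_frame <- function(x, ...) {
  cat("grouped_frame:", nrow(x), "groups,",
      length(unique(x$mol_id)), "molecules; box =",
      paste(signif(attr(x, "box"), 4), collapse = " x "), "nm\n")
  print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}

#' Map one atomistic frame to reduced-resolution molecular groups
#'
#' Each group's position is the mass-weighted center of its member atoms.
#' Hydrogens (atom names starting with `H`) are attached to the group of
#' the nearest heavy atom in the same molecule, so the shipped heavy-atom
#' schemes work for both united-atom and all-atom inputs.
#'
#' @param atoms data.frame with columns `name` (atom name), `kind`
#'   (molecule kind: `"POPC"`, `"TG"` or `"residue"`), `mol_id` (integer
#'   molecule/residue identifier), `x`, `y`, `z` (nm) and optionally
#'   `mass` (g/mol; guessed from names otherwise).
#' @param schemes List of grouping schemes, see [build_default_schemes()].
#' @param box Length-3 numeric, orthorhombic periodic box (nm).
#' @return A `grouped_frame`: data.frame with columns `mol_id`, `mol_kind`
#'   (`"PL"`, `"TG"` or `"protein"`), `label`, `group_kind`, `x`, `y`, `z`,
#'   `n_atoms`, `mass`, with the box as an attribute.
#' @export
map_frame <- function(atoms, schemes = build_default_schemes(), box) {
  stopifnot(is.data.frame(atoms), length(box) == 3, all(box > 0))
  if (is.null(atoms$mass)) atoms$mass <- atom_masses(atoms$name)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")

  scheme_kinds <- vapply(schemes, `[[`, "", "molecule_kind")
  out_kind <- c(POPC = "PL", TG = "TG", residue = "protein")

  res <- vector("list", 0L)
  for (key in unique(paste(atoms$kind, atoms$mol_id))) {
    sel <- paste(atoms$kind, atoms$mol_id) == key
    mol <- atoms[sel, , drop = FALSE]
    kind <- mol$kind[1L]
    mid <- mol$mol_id[1L]
    si <- match(kind, scheme_kinds)
    if (is.na(si))
      stop("no grouping scheme for molecule kind '", kind,
           "' (molecule ", mid, ")")
    sch <- schemes[[si]]

    is_h <- grepl("^[0-9]*H", mol$name)
    heavy <- which(!is_h)
    gidx <- rep(NA_integer_, nrow(mol))
    for (gi in seq_len(nrow(sch$groups))) {
      hit <- heavy[mol$name[heavy] %in% sch$groups$atoms[[gi]]]
      gidx[hit] <- gi
    }
    ## residue scheme: side chain is the complement of the backbone set
    if (kind == "residue") {
      sc_gi <- which(sch$groups$kind == "sidechain")
      gidx[heavy][is.na(gidx[heavy])] <- sc_gi
    }
    if (anyNA(gidx[heavy]))
      stop("unknown atom name(s) for ", kind, " molecule ", mid, ": ",
           paste(unique(mol$name[heavy][is.na(gidx[heavy])]), collapse = ", "))
    ## attach hydrogens to the nearest heavy atom's group
    if (any(is_h)) {
      if (length(heavy) == 0L)
        stop("molecule ", mid, " has only hydrogens")
      hx <- as.matrix(mol[is_h, c("x", "y", "z"), drop = FALSE])
      hv <- as.matrix(mol[heavy, c("x", "y", "z"), drop = FALSE])
      for (k in seq_len(nrow(hx))) {
        d2 <- colSums((t(hv) - hx[k, ])^2)
        gidx[which(is_h)[k]] <- gidx[heavy[which.min(d2)]]
      }
    }

    present <- sort(unique(gidx))
    ent <- data.frame(
      mol_id = mid,
      mol_kind = unname(out_kind[kind]),
      label = sch$groups$label[present],
      group_kind = sch$groups$kind[present],
      x = NA_real_, y = NA_real_, z = NA_real_,
      n_atoms = NA_integer_, mass = NA_real_,
      stringsAsFactors = FALSE
    )
    for (j in seq_along(present)) {
      a <- which(gidx == present[j])
      w <- mol$mass[a] / sum(mol$mass[a])
      ent$x[j] <- sum(w * mol$x[a])
      ent$y[j] <- sum(w * mol$y[a])
      ent$z[j] <- sum(w * mol$z[a])
      ent$n_atoms[j] <- length(a)
      ent$mass[j] <- sum(mol$mass[a])
    }
    res[[length(res) + 1L]] <- ent
  }
  .new_grouped_frame(do.call(rbind, res), box)
}

#' Map an atomistic trajectory to grouped frames
#'
#' @param coords List of coordinate matrices (n_atoms x 3, nm), one per
#'   frame, in the same atom order as `atoms`, or a 3d array
#'   (frames x atoms x 3).
#' @inheritParams map_frame
#' @return List of `grouped_frame` objects, frame order preserved.
#' @export
map_trajectory <- function(coords, atoms, schemes = build_default_schemes(),
                           box) {
  if (is.array(coords) && length(dim(coords)) == 3L)
    coords <- lapply(seq_len(dim(coords)[1L]),
                     function(i) coords[i, , , drop = TRUE])
  lapply(seq_along(coords), function(i) {
    xyz <- coords[[i]]
    if (nrow(xyz) != nrow(atoms))
      stop("frame ", i, ": ", nrow(xyz), " atoms, expected ", nrow(atoms))
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
    map_frame(atoms, schemes, box)
  })
}

#' Write / read grouped frames as a delimited table
#'
#' One long CSV with a `frame` column; the box is stored in the header
#' comment line.
#'
#' @param frames List of `grouped_frame` objects (or one frame).
#' @param file Path to the CSV file.
#' @export
write_grouped <- function(frames, file) {
  if (inherits(frames, "grouped_frame")) frames <- list(frames)
  box <- attr(frames[[1L]], "box")
  tab <- do.call(rbind, lapply(seq_along(frames), function(i)
    cbind(frame = i, as.data.frame(frames[[i]]))))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# box_nm %.10g %.10g %.10g", box[1], box[2], box[3]), con)
  write.table(tab, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_grouped
#' @export
read_grouped <- function(file) {
  hdr <- readLines(file, n = 1L)
  box <- as.numeric(strsplit(sub("^# box_nm ", "", hdr), " ")[[1L]])
  tab <- read.table(file, sep = ",", header = TRUE, skip = 1L,
                    stringsAsFactors = FALSE)
  lapply(split(tab, tab$frame), function(d)
    .new_grouped_frame(d[, setdiff(names(d), "frame")], box))
}
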