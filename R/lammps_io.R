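## Export of a CG system to LAMMPS input formats (real units: A, fs,
## kcal/mol) and a reader for LAMMPS text dumps.

.merge_types <- function(d, digits = 4L) {
  if (nrow(d) == 0L)
    return(list(types = integer(0), coeffs = d[0, , drop = FALSE]))
  key <- apply(round(d[, setdiff(names(d), c("i", "j", "l")), drop = FALSE],
                     digits), 1L, paste, collapse = "_")
  u <- !duplicated(key)
  list(types = match(key, key[u]), coeffs = d[u, , drop = FALSE])
}

#' Export a CG system as LAMMPS inputs
#'
#' Writes `system.data` (atoms with mass 200 g/mol and zero charge, bonds
#' -- lipid bonds and elastic springs merged into harmonic bond types --
#' and angles, coordinates in Angstrom), `pairs.table` (one tabulated
#' potential section per interaction-class pair present, scaled by the
#' interaction table) and `in.cg`, an input-script skeleton encoding the
#' 50 fs time step, the 310 K / 100 ps Langevin thermostat and the 1.5 nm
#' nonbonded cutoff.  LAMMPS' `bond_style harmonic` uses the same
#' `K (r - r0)^2` convention as this package, so spring constants are
#' written unchanged in kcal/mol/A^2.
#'
#' @param sys A `cg_system` with a box.
#' @param dir Output directory (created if needed).
#' @param table Interaction table.
#' @param params A [sim_params()].
#' @param table_n Grid points per tabulated pair.
#' @return Invisibly, the paths of the written files.
#' @export
export_lammps <- function(sys, dir, table = build_interaction_table(),
                          params = sim_params(), table_n = 1000L) {
  stopifnot(!is.null(sys$box))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cls <- bead_class(sys)
  present <- levels(cls)[levels(cls) %in% unique(as.character(cls))]
  at <- match(as.character(cls), present)

  bonds_all <- rbind(sys$bonds, sys$springs)
  bt <- .merge_types(bonds_all)
  an <- .merge_types(sys$angles)

  data_file <- file.path(dir, "system.data")
  con <- file(data_file, "w")
  w <- function(...) writeLines(sprintf(...), con)
  w("LAMMPS data file generated by droplens")
  w("")
  w("%d atoms", n_beads(sys))
  w("%d bonds", nrow(bonds_all))
  w("%d angles", nrow(sys$angles))
  w("")
  w("%d atom types", length(present))
  if (nrow(bonds_all)) w("%d bond types", nrow(bt$coeffs))
  if (nrow(sys$angles)) w("%d angle types", nrow(an$coeffs))
  w("")
  w("0.0 %.6f xlo xhi", sys$box[1L] * 10)
  w("0.0 %.6f ylo yhi", sys$box[2L] * 10)
  w("0.0 %.6f zlo zhi", sys$box[3L] * 10)
  w("")
  w("Masses")
  w("")
  for (t in seq_along(present)) w("%d 200.0  # %s", t, present[t])
  w("")
  w("Atoms  # molecular")
  w("")
  for (i in seq_len(n_beads(sys)))
    w("%d %d %d %.6f %.6f %.6f", i, sys$mol[i], at[i],
      sys$x[i, 1L] * 10, sys$x[i, 2L] * 10, sys$x[i, 3L] * 10)
  if (nrow(bonds_all)) {
    w("")
    w("Bond Coeffs  # harmonic: K (kcal/mol/A^2), r0 (A)")
    w("")
    for (t in seq_len(nrow(bt$coeffs)))
      w("%d %.6f %.6f", t, bt$coeffs$k[t], bt$coeffs$r0[t] * 10)
    w("")
    w("Bonds")
    w("")
    for (b in seq_len(nrow(bonds_all)))
      w("%d %d %d %d", b, bt$types[b], bonds_all$i[b], bonds_all$j[b])
  }
  if (nrow(sys$angles)) {
    w("")
    w("Angle Coeffs  # harmonic: K (kcal/mol/rad^2), theta0 (deg)")
    w("")
    for (t in seq_len(nrow(an$coeffs)))
      w("%d %.6f %.4f", t, an$coeffs$k[t], an$coeffs$theta0[t] * 180 / pi)
    w("")
    w("Angles")
    w("")
    for (b in seq_len(nrow(sys$angles)))
      w("%d %d %d %d %d", b, an$types[b], sys$angles$i[b], sys$angles$j[b],
        sys$angles$l[b])
  }
  close(con)

  ## tabulated pair potentials, in A / kcal/mol / kcal/mol/A
  table_file <- file.path(dir, "pairs.table")
  con <- file(table_file, "w")
  w <- function(...) writeLines(sprintf(...), con)
  w("# droplens tabulated CG pair potentials (A, kcal/mol, kcal/mol/A)")
  r <- seq(0.05, params$cutoff, length.out = table_n)
  for (a in seq_along(present)) for (b in a:length(present)) {
    f <- table[present[a], present[b]]
    pp <- pair_potential(r, f, params)
    w("")
    w("PAIR_%d_%d", a, b)
    w("N %d R %.6f %.6f", table_n, r[1L] * 10, params$cutoff * 10)
    w("")
    for (k in seq_len(table_n))
      w("%d %.6f %.10g %.10g", k, r[k] * 10, pp$energy[k], pp$force[k] / 10)
  }
  close(con)

  ## input-script skeleton
  in_file <- file.path(dir, "in.cg")
  pc <- vapply(seq_along(present), function(a)
    paste(vapply(a:length(present), function(b)
      sprintf("pair_coeff %d %d pairs.table PAIR_%d_%d", a, b, a, b), ""),
      collapse = "\n"), "")
  writeLines(c(
    "# CG seipin/lipid system -- generated skeleton",
    "units real",
    "atom_style molecular",
    "boundary p p p",
    "read_data system.data",
    sprintf("pair_style table linear %d", table_n),
    pc,
    if (nrow(bonds_all)) "bond_style harmonic",
    if (nrow(sys$angles)) "angle_style harmonic",
    "neighbor 2.0 bin",
    sprintf("timestep %g", params$dt),
    sprintf("fix 1 all langevin %g %g %g %d", params$temperature,
            params$temperature, params$damping, params$seed),
    "fix 2 all nve",
    "thermo 1000",
    "dump 1 all custom 10000 traj.dump id type xu yu zu",
    "run 100000000"
  ), in_file)

  invisible(c(data = data_file, tables = table_file, input = in_file))
}

#' Read back a LAMMPS data file
#'
#' Minimal parser used for round-trip checks of [export_lammps()]: counts,
#' masses, atoms, bonds and angles.
#'
#' @param file Path to a LAMMPS data file.
#' @return List with `counts` (atoms/bonds/angles/types), `masses`,
#'   `atoms` (data.frame, coordinates converted to nm), `bonds`, `angles`.
#' @export
read_lammps_data <- function(file) {
  ln <- readLines(file)
  grab <- function(pat) {
    m <- grep(pat, ln, value = TRUE)
    if (length(m) == 0L) return(0L)
    as.integer(sub(paste0("^\\s*(\\d+)\\s+", pat, ".*"), "\\1", m[1L]))
  }
  counts <- c(atoms = grab("atoms"), bonds = grab("bonds"),
              angles = grab("angles"), atom_types = grab("atom types"))
  section <- function(name, ncol) {
    i <- grep(paste0("^", name, "\\b"), ln)
    if (length(i) == 0L) return(NULL)
    body <- ln[(i[1L] + 2L):length(ln)]
    stop_at <- which(body == "" | grepl("^[A-Z]", body))[1L]
    if (!is.na(stop_at)) body <- body[seq_len(stop_at - 1L)]
    body <- body[nzchar(body)]
    do.call(rbind, lapply(strsplit(sub("#.*", "", body), "\\s+"),
                          function(v) as.numeric(v[nzchar(v)][seq_len(ncol)])))
  }
  masses <- section("Masses", 2L)
  atoms <- section("Atoms", 6L)
  bonds <- section("Bonds", 4L)
  angles <- section("Angles", 5L)
  atoms <- data.frame(id = atoms[, 1L], mol = atoms[, 2L], type = atoms[, 3L],
                      x = atoms[, 4L] / 10, y = atoms[, 5L] / 10,
                      z = atoms[, 6L] / 10)
  list(counts = counts,
       masses = if (!is.null(masses))
         data.frame(type = masses[, 1L], mass = masses[, 2L]),
       atoms = atoms[order(atoms$id), ],
       bonds = if (!is.null(bonds))
         data.frame(id = bonds[, 1L], type = bonds[, 2L],
                    i = bonds[, 3L], j = bonds[, 4L]),
       angles = if (!is.null(angles))
         data.frame(id = angles[, 1L], type = angles[, 2L], i = angles[, 3L],
                    j = angles[, 4L], l = angles[, 5L]))
}

#' Read a LAMMPS text dump
#'
#' Parses `dump custom` output with at least `id type x y z` (or
#' `xu yu zu`) columns; coordinates are converted from Angstrom to nm and
#' beads are returned in stable id order.
#'
#' @param file Path to the dump file.
#' @return List of frames, each a list with `step`, `box` (nm, or NULL)
#'   and `atoms` (data.frame `id, type, x, y, z`).
#' @export
read_lammps_dump <- function(file) {
  ln <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(ln)) {
    if (!grepl("^ITEM: TIMESTEP", ln[i]))
      stop("malformed dump frame near line ", i, " of ", file)
    step <- as.integer(ln[i + 1L])
    i <- i + 2L
    if (!grepl("^ITEM: NUMBER OF ATOMS", ln[i]))
      stop("malformed dump frame near line ", i, " of ", file)
    na <- as.integer(ln[i + 1L])
    i <- i + 2L
    box <- NULL
    if (grepl("^ITEM: BOX BOUNDS", ln[i])) {
      b <- do.call(rbind, strsplit(ln[i + 1:3], "\\s+"))
      box <- (as.numeric(b[, 2L]) - as.numeric(b[, 1L])) / 10
      i <- i + 4L
    }
    if (!grepl("^ITEM: ATOMS", ln[i]))
      stop("malformed dump frame near line ", i, " of ", file)
    cols <- strsplit(sub("^ITEM: ATOMS ", "", ln[i]), "\\s+")[[1L]]
    body <- ln[i + seq_len(na)]
    m <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
    colnames(m) <- cols
    pick <- function(a, b) if (a %in% cols) a else b
    d <- data.frame(id = m[, "id"], type = m[, "type"],
                    x = m[, pick("x", "xu")] / 10,
                    y = m[, pick("y", "yu")] / 10,
                    z = m[, pick("z", "zu")] / 10)
    frames[[length(frames) + 1L]] <- list(step = step, box = box,
                                          atoms = d[order(d$id), ])
    i <- i + na + 1L
  }
  frames
}
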