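test_that("default schemes have the canonical group structure", {
  sch <- build_default_schemes()

  expect_equal(nrow(sch$POPC$groups), 11L)
  expect_equal(sum(sch$POPC$groups$kind == "tail"), 8L)
  expect_equal(nrow(sch$TG$groups), 13L)
  expect_equal(sum(sch$TG$groups$kind == "tail"), 12L)
  expect_equal(sum(sch$TG$groups$kind == "glycerol"), 1L)
  expect_equal(nrow(sch$residue$groups), 2L)
  expect_setequal(sch$residue$groups$kind, c("backbone", "sidechain"))

  ## member atom sets partition the molecule (no atom in two groups)
  for (s in sch[c("POPC", "TG")]) {
    all_atoms <- unlist(s$groups$atoms)
    expect_equal(anyDuplicated(all_atoms), 0L)
  }
  ## heavy-atom totals match the molecular formulas (POPC 52, triolein 63)
  expect_length(unlist(sch$POPC$groups$atoms), 52L)
  expect_length(unlist(sch$TG$groups$atoms), 63L)
})

test_that("map_frame produces the right group counts and centers", {
  sch <- build_default_schemes()
  box <- c(10, 10, 10)

  gf <- map_frame(make_molecule_atoms("POPC"), sch, box)
  expect_equal(nrow(gf), 11L)
  expect_equal(unique(gf$mol_kind), "PL")

  gf <- map_frame(make_molecule_atoms("TG"), sch, box)
  expect_equal(nrow(gf), 13L)
  expect_equal(sum(gf$group_kind == "tail"), 12L)

  gf <- map_frame(make_residue_atoms(), sch, box)
  expect_equal(nrow(gf), 2L)

  ## degenerate: a single-atom group sits exactly on its atom
  at <- make_residue_atoms()
  bb <- at[at$name %in% c("N", "CA", "C", "O"), ]
  one_sc <- at[at$name == "CB", ]
  gf <- map_frame(rbind(bb, one_sc), sch, box)
  sc <- gf[gf$group_kind == "sidechain", ]
  expect_equal(c(sc$x, sc$y, sc$z), c(one_sc$x, one_sc$y, one_sc$z))
})

test_that("group centers are mass-weighted means (hand-computed oracle)", {
  ## 3-atom toy residue, masses 1, 1, 2, split 2/1 backbone/sidechain:
  ## positions chosen so the weighted means are easy to hand-check
  at <- data.frame(name = c("N", "CA", "CB"), kind = "residue", mol_id = 1L,
                   x = c(0, 1, 5), y = c(0, 2, 1), z = c(0, 0, 3),
                   mass = c(1, 1, 2))
  gf <- map_frame(at, box = c(20, 20, 20))
  bb <- gf[gf$group_kind == "backbone", ]
  sc <- gf[gf$group_kind == "sidechain", ]
  expect_equal(c(bb$x, bb$y, bb$z), c(0.5, 1, 0))   # (1*0 + 1*1) / 2 etc.
  expect_equal(c(sc$x, sc$y, sc$z), c(5, 1, 3))
  expect_equal(bb$mass + sc$mass, sum(at$mass))     # mass conservation
})

test_that("grouped center of mass equals the atomistic center of mass", {
  sch <- build_default_schemes()
  for (kind in c("POPC", "TG")) {
    at <- make_molecule_atoms(kind, seed = 9L)
    at$mass <- atom_masses(at$name)
    gf <- map_frame(at, sch, c(10, 10, 10))
    com_at <- colSums(at$mass * as.matrix(at[, c("x", "y", "z")])) /
      sum(at$mass)
    com_gr <- colSums(gf$mass * cbind(gf$x, gf$y, gf$z)) / sum(gf$mass)
    expect_equal(unname(com_gr), unname(com_at), tolerance = 1e-12)
    expect_equal(sum(gf$mass), sum(at$mass))
  }
})

test_that("hydrogens are attached to their nearest heavy atom's group", {
  at <- data.frame(name = c("N", "CA", "C", "O", "CB", "HB1", "HB2"),
                   kind = "residue", mol_id = 1L,
                   x = c(0, 0.1, 0.2, 0.3, 2, 2.05, 1.95),
                   y = 0, z = 0)
  gf <- map_frame(at, box = c(10, 10, 10))
  sc <- gf[gf$group_kind == "sidechain", ]
  expect_equal(sc$n_atoms, 3L)  # CB + its two hydrogens
})

test_that("mapping errors are informative", {
  sch <- build_default_schemes()
  at <- make_molecule_atoms("POPC")
  at$name[1L] <- "XX9"
  expect_error(map_frame(at, sch, c(10, 10, 10)), "XX9")
  at2 <- make_molecule_atoms("POPC")
  at2$kind <- "CHOL"
  expect_error(map_frame(at2, sch, c(10, 10, 10)), "CHOL")
})

test_that("map_trajectory preserves frame order and validates atom counts", {
  sch <- build_default_schemes()
  at <- make_molecule_atoms("TG")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  frames <- map_trajectory(list(xyz, xyz + 1), at, sch, c(10, 10, 10))
  expect_length(frames, 2L)
  expect_equal(frames[[2L]]$x, frames[[1L]]$x + 1)
  expect_error(map_trajectory(list(xyz, xyz[-1, ]), at, sch, c(10, 10, 10)),
               "frame 2")
})

test_that("grouped frames survive a write/read round trip", {
  sch <- build_default_schemes()
  at <- make_molecule_atoms("POPC")
  gf <- map_frame(at, sch, c(10, 10, 10))
  f <- tempfile(fileext = ".csv")
  write_grouped(list(gf, gf), f)
  back <- read_grouped(f)
  expect_length(back, 2L)
  expect_equal(back[[1L]]$x, gf$x, tolerance = 1e-9)
  expect_equal(attr(back[[1L]], "box"), c(10, 10, 10))
})
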