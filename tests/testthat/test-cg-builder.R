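test_that("protein CG mapping packs 4 residues per bead", {
  ## the seipin construct: 243 residues -> 61 beads (60 blocks of 4 + 3)
  res <- data.frame(subunit = 1L, resid = 23:265,
                    x = rnorm(243), y = rnorm(243), z = rnorm(243))
  expect_equal(n_beads(map_protein_cg(res)), 61L)

  ## 4 coincident residues collapse onto one bead at that point
  res4 <- data.frame(subunit = 1L, resid = 1:4, x = 1, y = 2, z = 3)
  cg <- map_protein_cg(res4)
  expect_equal(n_beads(cg), 1L)
  expect_equal(cg$x[1L, ], c(1, 2, 3))

  ## 8 residues on a line at unit spacing -> 2 beads at the block centroids
  res8 <- data.frame(subunit = 1L, resid = 1:8, x = 0:7, y = 0, z = 0)
  cg <- map_protein_cg(res8)
  expect_equal(cg$x[, 1L], c(1.5, 5.5))

  ## beads inherit mass 200 g/mol and zero charge
  expect_true(all(cg$mass == 200))
  expect_true(all(cg$charge == 0))

  ## missing residues are reported by subunit
  bad <- res[-10, ]
  expect_error(map_protein_cg(bad), "subunit 1")
})

test_that("ENM construction matches a brute-force distance scan", {
  ## pair cases
  x2 <- rbind(c(0, 0, 0), c(1.0, 0, 0))
  s <- build_enm(x2, sc = 0.2, cutoff = 1.5)
  expect_equal(nrow(s), 1L)
  expect_equal(s$r0, 1.0)
  expect_equal(s$k, 0.2)
  expect_equal(nrow(build_enm(rbind(c(0, 0, 0), c(2, 0, 0)), cutoff = 1.5)),
               0L)

  ## 5 collinear beads at 1.0 nm spacing, cutoff 1.5 -> neighbors only
  x5 <- cbind(0:4, 0, 0)
  expect_equal(nrow(build_enm(x5, cutoff = 1.5)), 4L)

  ## random cloud: spring set equals the O(n^2) scan, symmetric
  set.seed(21)
  x <- matrix(runif(90, 0, 3), 30, 3)
  s <- build_enm(x, sc = 2.0, cutoff = 1.5)
  brute <- 0L
  for (i in 1:29) for (j in (i + 1L):30)
    if (sqrt(sum((x[i, ] - x[j, ])^2)) < 1.5) brute <- brute + 1L
  expect_equal(nrow(s), brute)
  expect_true(all(s$i < s$j))
  expect_true(all(s$k > 0))
  expect_equal(anyDuplicated(paste(s$i, s$j)), 0L)
})

test_that("24 proteinized PLs are added inside the HH ring and networked", {
  cage <- gen_idealized_seipin(seed = 2L)
  full <- add_proteinized_pls(cage, seed = 2L)

  pmol <- unique(full$mol[full$flags$proteinized_pl])
  expect_length(pmol, 24L)
  expect_true(all(full$type[full$flags$proteinized_pl] %in%
                  c("PL_head", "PL_int", "PL_tail")))

  ## lumenal orientation: heads are the deepest beads of each molecule
  for (m in pmol[1:5]) {
    rows <- which(full$mol == m)
    expect_equal(full$type[rows[which.min(full$x[rows, 3L])]], "PL_head")
  }
  ## heads stay inside the HH ring radius
  heads <- full$flags$proteinized_pl & full$type == "PL_head"
  expect_true(all(sqrt(rowSums(full$x[heads, 1:2]^2)) < 2.0))

  ## every proteinized molecule is tied to the cage by >= 1 spring
  for (m in pmol) {
    rows <- which(full$mol == m)
    sp <- full$springs[full$springs$i %in% rows | full$springs$j %in% rows, ]
    partners <- setdiff(c(sp$i, sp$j), rows)
    expect_true(any(full$type[partners] == "PROT"))
  }

  ## n = 0 leaves the model untouched
  expect_identical(add_proteinized_pls(cage, n = 0L), cage)
})

test_that("oligomer truncation removes subunits or TM segments", {
  cage <- gen_idealized_seipin(seed = 3L)
  cage <- build_enm(cage, sc = 0.2, cutoff = 1.5)

  five <- truncate_oligomer(cage, n = 6L)
  expect_equal(length(unique(five$subunit[!is.na(five$subunit)])), 5L)
  ## removed contiguously: remaining subunits are a contiguous arc
  expect_equal(sort(unique(five$subunit[!is.na(five$subunit)])), 7:11)

  expect_identical(truncate_oligomer(cage, n = 0L), cage)
  expect_error(truncate_oligomer(cage, n = 11L), "cannot remove")

  lum <- truncate_oligomer(cage, "lumenal_only")
  expect_equal(sum(lum$flags$tm_segment), 0L)
  expect_equal(sum(lum$flags$tm_tip), 0L)
  ## springs are the induced subgraph: all endpoints survive
  expect_true(all(c(lum$springs$i, lum$springs$j) <= n_beads(lum)))
  ## spring count equals springs of the original with both ends lumenal
  keep <- which(!cage$flags$tm_segment)
  expect_equal(nrow(lum$springs),
               sum(cage$springs$i %in% keep & cage$springs$j %in% keep))
})

test_that("interaction table defaults encode the attraction rules", {
  tab <- build_interaction_table()
  expect_equal(tab["P_phobic", "PL_tail"], 1)
  expect_equal(tab["P_interface", "PL_int"], 1.5)
  expect_equal(tab["P_tg_hh", "TG_tail"], 1.5)
  expect_equal(tab["P_tg_hh", "TG_gly"], 1.5)
  expect_equal(tab["P_tg_tm", "TG_tail"], 1.5)
  expect_equal(tab["P_tip", "PL_int"], 1.5)
  expect_equal(tab["PL_head", "PL_head"], 0)
  expect_true(isSymmetric(unclass(tab)))

  ## per subunit: 2 HH beads + 4 central beads per TM segment attract TG
  cage <- gen_idealized_seipin(seed = 4L)
  per_sub <- function(fl) sum(fl[cage$subunit == 1L])
  expect_equal(per_sub(cage$flags$tg_attract_hh), 2L)
  expect_equal(per_sub(cage$flags$tg_attract_tm), 8L)

  ## overrides and the tip scaling knob
  tab0 <- build_interaction_table(overrides = list("P_tip|PL_int" = 0))
  expect_equal(tab0["PL_int", "P_tip"], 0)
  tabr <- build_interaction_table(tip_scaling = 0.2)
  expect_equal(tabr["P_tip", "PL_head"], 0.2)
  expect_error(build_interaction_table(overrides = list("P_tip|PL_int" = -1)),
               "negative")
  expect_error(build_interaction_table(overrides = list("foo|bar" = 1)),
               "unknown")
})

test_that("spherical bilayers have leaflet geometry and TG stoichiometry", {
  v <- build_spherical_bilayer(diameter = 30, tg_percent = 0, seed = 1L)
  expect_equal(sum(v$type %in% c("TG_gly", "TG_tail")), 0L)

  v2 <- build_spherical_bilayer(diameter = 30, tg_percent = 2, seed = 1L)
  n_tg <- length(unique(v2$mol[v2$type == "TG_gly"]))
  n_pl_built <- length(unique(v2$mol[v2$type == "PL_head"]))
  ## mole fraction ~2% of all lipids (a few PLs are pruned around TG)
  expect_lt(abs(100 * n_tg / (n_tg + n_pl_built) - 2), 0.35)

  ## outer-leaflet heads sit outside all outer-leaflet tails
  ctr <- v2$box / 2
  r <- sqrt(rowSums(sweep(v2$x, 2L, ctr)^2))
  r_mid <- (max(r[v2$type == "PL_head"]) + min(r[v2$type == "PL_head"])) / 2
  outer <- r > r_mid & v2$type %in% c("PL_head", "PL_tail")
  expect_gt(min(r[outer & v2$type == "PL_head"]),
            max(r[outer & v2$type == "PL_tail"]))

  ## reproducible bit-for-bit under a seed
  expect_identical(v2$x,
                   build_spherical_bilayer(diameter = 30, tg_percent = 2,
                                           seed = 1L)$x)
})

test_that("protein embedding removes exactly the clashing lipids", {
  v <- build_spherical_bilayer(diameter = 30, tg_percent = 2, seed = 2L)
  cage <- gen_idealized_seipin(seed = 2L)
  sys <- embed_protein(v, cage, clash = 0.5)

  n_lip_before <- length(unique(v$mol))
  n_lip_after <- length(unique(sys$mol[sys$type != "PROT"]))
  expect_lt(n_lip_after, n_lip_before)

  ## no remaining lipid bead within the clash cutoff of the protein
  lip <- sys$x[sys$type != "PROT", , drop = FALSE]
  prot <- sys$x[sys$type == "PROT", , drop = FALSE]
  dmin <- min(apply(prot, 1L, function(p)
    min(sqrt(colSums((t(lip) - p)^2)))))
  expect_gt(dmin, 0.5)
})
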