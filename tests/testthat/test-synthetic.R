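test_that("generators are deterministic per seed and carry ground truth", {
  a <- gen_bilayer_patch(100, n_tg = 4, mode = "lens", seed = 3L)
  b <- gen_bilayer_patch(100, n_tg = 4, mode = "lens", seed = 3L)
  c2 <- gen_bilayer_patch(100, n_tg = 4, mode = "lens", seed = 4L)
  expect_identical(a$x, b$x)
  expect_false(identical(a$x, c2$x))
  expect_equal(attr(a, "ground_truth")$kind, "bilayer_patch")

  t1 <- gen_tg_cluster("sphere", 100L, seed = 5L)
  expect_identical(t1, gen_tg_cluster("sphere", 100L, seed = 5L))

  w <- gen_brownian(10, c(free = 1), n_frames = 20, dt_us = 0.01, seed = 6L)
  expect_identical(w$coords,
                   gen_brownian(10, c(free = 1), n_frames = 20,
                                dt_us = 0.01, seed = 6L)$coords)
  expect_equal(attr(w, "ground_truth")$D, c(free = 1))
})

test_that("bilayer patches deliver the advertised TG phase state", {
  ## dissolved: all singletons -> nucleation 100/n %
  p1 <- gen_bilayer_patch(800, n_tg = 10, mode = "dissolved", seed = 2L)
  expect_equal(nucleation_percentage(cluster_tg(p1)), 10)

  ## lens: one cluster -> 100 %
  p2 <- gen_bilayer_patch(400, n_tg = 100, mode = "lens", seed = 2L)
  expect_equal(nucleation_percentage(cluster_tg(p2)), 100)

  ## no TG requested -> no TG beads
  p0 <- gen_bilayer_patch(100, tg_percent = 0, seed = 2L)
  expect_equal(sum(p0$type %in% c("TG_gly", "TG_tail")), 0L)

  ## infeasible dissolved placement fails with advice
  expect_error(gen_bilayer_patch(100, n_tg = 50, mode = "dissolved",
                                 seed = 2L), "lens")

  ## leaflet geometry: heads outermost in each leaflet
  up <- p1$type == "PL_head" & p1$x[, 3L] > p1$box[3L] / 2
  up_tail <- p1$type == "PL_tail" & p1$x[, 3L] > p1$box[3L] / 2
  expect_gt(min(p1$x[up, 3L]), max(p1$x[up_tail, 3L]))
})

test_that("Brownian generator honours D = 0 and confinement", {
  still <- gen_brownian(5, c(free = 0), n_frames = 50, dt_us = 0.01,
                        seed = 7L)
  expect_equal(max(abs(sweep(still$coords, c(2, 3),
                             still$coords[1, , ]))), 0)

  trapped <- gen_brownian(100, c(inner = 1), n_frames = 500, dt_us = 0.01,
                          trap = 20, seed = 8L)
  m <- msd(trapped, max_lag = 200)
  late <- fit_diffusion(m, fit_window = c(0.7, 1.0))
  expect_lt(late$D, 0.05)  # plateau: late-lag slope ~ 0
})

test_that("the idealized seipin cage is ring-symmetric and annotated", {
  cage <- gen_idealized_seipin(n_subunits = 11L, jitter = 0, seed = 9L)
  expect_equal(length(unique(cage$subunit)), 11L)
  ## identical per-subunit bead budget and flag counts
  tab <- table(cage$subunit)
  expect_true(all(tab == tab[1L]))
  for (f in c("tg_attract_hh", "tg_attract_tm", "tm_tip", "tm_segment")) {
    per <- tapply(cage$flags[[f]], cage$subunit, sum)
    expect_true(all(per == per[1L]))
  }
  ## C_11 symmetry: subunit 2 is subunit 1 rotated by 2 pi / 11
  th <- 2 * pi / 11
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s1 <- cage$x[cage$subunit == 1L, ]
  s2 <- cage$x[cage$subunit == 2L, ]
  expect_equal(s1 %*% t(R), s2, tolerance = 1e-9)

  ## TM tips sit on the cytosolic membrane surface (z = +2 nm)
  expect_lt(max(abs(cage$x[cage$flags$tm_tip, 3L] - 2)), 0.1)

  ## single-subunit control
  one <- gen_idealized_seipin(n_subunits = 1L, seed = 9L)
  expect_equal(length(unique(one$subunit)), 1L)
  expect_equal(n_beads(one), n_beads(cage) / 11L)
})

test_that("patches with an embedded cage remain simulation-ready", {
  patch <- gen_bilayer_patch(480, n_tg = 16, mode = "dissolved",
                             box_z = 18, seed = 10L)
  cage <- gen_idealized_seipin(hh_radius = 1.2, lum_radius = 2.0,
                               tip_radius = 4.2, seed = 10L)
  cage <- add_proteinized_pls(cage, n = 6L, hh_radius = 1.2, seed = 10L)
  sys <- embed_protein_patch(patch, cage, clash = 0.45)
  ## lipid count: patch total minus clashing molecules
  expect_lt(length(unique(sys$mol)), length(unique(patch$mol)) +
                                     length(unique(cage$mol)))
  ## forces are finite after a short relaxation (no overlaps left)
  m <- minimize_cg(sys, params = sim_params())
  expect_true(is.finite(attr(m, "epot")))
})
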