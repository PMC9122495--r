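test_that("TG clustering handles the elementary cases", {
  ## one molecule -> one cluster of size 1
  x1 <- matrix(rnorm(12, sd = 0.1), 4, 3)
  cl <- cluster_tg(x1, rep(1L, 4))
  expect_equal(cl$sizes, 1L)

  ## two molecules with min bead distance 3 nm -> two clusters
  x2 <- rbind(matrix(0.1 * rnorm(12), 4, 3),
              matrix(0.1 * rnorm(12), 4, 3) + 5)
  cl2 <- cluster_tg(x2, rep(1:2, each = 4L))
  expect_equal(length(cl2$sizes), 2L)

  ## ... but one cluster when any bead pair comes within the cutoff
  x3 <- x2
  x3[5, ] <- x3[1, ] + c(1.9, 0, 0)
  cl3 <- cluster_tg(x3, rep(1:2, each = 4L))
  expect_equal(length(cl3$sizes), 1L)

  expect_error(cluster_tg(matrix(0, 0, 3), integer(0)), "no TG")
})

test_that("clustering equals the brute-force union-find oracle", {
  set.seed(14)
  for (rep in 1:100) {
    n_mol <- sample(5:50, 1L)
    box <- c(12, 12, 12)
    centers <- matrix(runif(3 * n_mol, 0, 12), n_mol, 3)
    x <- centers[rep(seq_len(n_mol), each = 2L), ] +
      matrix(rnorm(6 * n_mol, 0, 0.3), 2L * n_mol, 3)
    mol <- rep(seq_len(n_mol), each = 2L)
    use_box <- rep %% 2L == 0L
    cl <- cluster_tg(x, mol, cutoff = 2, box = if (use_box) box)
    want <- oracle_cluster(x, mol, 2, box = if (use_box) box)
    ## same partition (labels may be permuted)
    expect_equal(length(cl$sizes), length(unique(want)))
    got <- as.integer(cl$labels)
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("nucleation percentage is the largest-cluster share", {
  mk <- function(sizes) {
    labels <- rep(seq_along(sizes), sizes)
    structure(list(labels = labels, sizes = sizes,
                   largest = which.max(sizes),
                   n_molecules = sum(sizes)),
              class = "cluster_result")
  }
  expect_equal(nucleation_percentage(mk(c(10))), 100)
  expect_equal(nucleation_percentage(mk(c(1, 1))), 50)
  expect_equal(nucleation_percentage(mk(c(7, 2, 1))), 70)
})

test_that("merging clusters never decreases the nucleation percentage", {
  set.seed(15)
  a <- matrix(rnorm(30, sd = 0.5), 10, 3)
  b <- matrix(rnorm(30, sd = 0.5), 10, 3) + 10
  mol <- c(rep(1:5, each = 2), rep(6:10, each = 2))  # 2 beads/molecule
  far <- nucleation_percentage(cluster_tg(rbind(a, b), mol))
  near <- nucleation_percentage(cluster_tg(rbind(a, b - 9), mol))
  expect_gte(near, far)
  expect_equal(near, 100)
})

test_that("anisotropy reproduces its sphere/disc/rod limits", {
  ball <- gen_tg_cluster("sphere", 10000L, size = 5, seed = 2L)
  disc <- gen_tg_cluster("disc", 10000L, size = 5, thickness = 0.005,
                         seed = 2L)
  rod <- gen_tg_cluster("rod", 10000L, size = 5, thickness = 0.005,
                        seed = 2L)
  expect_lt(anisotropy(ball), 0.01)
  expect_lt(abs(anisotropy(disc) - 0.25), 0.01)
  expect_gt(anisotropy(rod), 0.95)

  ## exact line: kappa^2 = 1
  line <- cbind(seq(0, 1, length.out = 50L), 0, 0)
  expect_equal(anisotropy(line), 1, tolerance = 1e-12)

  ## invariant under rigid rotation + translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(anisotropy(disc %*% t(R) + 3), anisotropy(disc),
               tolerance = 1e-10)

  expect_error(anisotropy(matrix(1, 5, 3)), "degenerate")
})

test_that("neck diameter is twice the mean tip radius about the ring axis", {
  ## 22 tips exactly on a circle of radius 7
  ang <- 2 * pi * seq_len(22L) / 22
  tips <- cbind(7 * cos(ang), 7 * sin(ang), 2)
  expect_equal(neck_diameter(tips), 14, tolerance = 1e-9)

  ## two concentric circles r = 6 and 8, equal counts -> mean radius 7
  tips2 <- rbind(cbind(6 * cos(ang), 6 * sin(ang), 2),
                 cbind(8 * cos(ang), 8 * sin(ang), 2))
  expect_equal(neck_diameter(tips2), 14, tolerance = 1e-9)

  ## jittered circle stays within 0.1 nm of the true diameter
  set.seed(16)
  tips3 <- tips + matrix(rnorm(66, 0, 0.1), 22, 3)
  expect_lt(abs(neck_diameter(tips3) - 14), 0.1)

  ## works off the full cage via the tm_tip flags and its principal axis
  cage <- gen_idealized_seipin(tip_radius = 7, seed = 5L)
  expect_lt(abs(neck_diameter(cage) - 14), 0.2)

  expect_error(neck_diameter(tips[1:2, ]), "3")
})

test_that("RMSF matches closed forms and the harmonic-network oracle", {
  ## rigid ensemble: all zero
  x0 <- matrix(rnorm(30), 10, 3)
  rigid <- array(rep(x0, each = 50L), c(50, 10, 3))
  expect_equal(max(rmsf(rigid)), 0)

  ## isotropic Gaussian jitter: RMSF = sigma * sqrt(3)
  set.seed(17)
  ens <- rigid
  for (s in 1:50) ens[s, , ] <- x0 + matrix(rnorm(30, 0, 0.2), 10, 3)
  expect_equal(mean(rmsf(ens)), 0.2 * sqrt(3), tolerance = 0.05)

  ## network-generated ensemble vs the analytic normal-mode fluctuations
  net <- grid_network()
  nens <- gen_gaussian_ensemble(net$x, net$springs, n_samples = 4000L,
                                seed = 18L)
  expect_lt(max(abs(rmsf(nens) / network_rmsf(net$x, net$springs) - 1)),
            0.05)

  expect_error(rmsf(rigid[1L, , , drop = FALSE]), "2 samples")
})

test_that("the time series tags coalescence jumps and slow ripening", {
  ## synthetic frames: singletons, then a sudden merge of most molecules
  mk_frame <- function(spread_groups) {
    centers <- do.call(rbind, lapply(seq_along(spread_groups), function(g)
      matrix(rep(c(10 * g, 0, 0), each = spread_groups[g]), ncol = 3) +
        matrix(runif(3 * spread_groups[g], 0, 1.2),
               spread_groups[g], 3)))
    list(x = centers, mol = seq_len(sum(spread_groups)))
  }
  set.seed(19)
  frames <- list(mk_frame(c(5, 5)), mk_frame(c(5, 5)), mk_frame(c(10)))
  ts <- metrics_timeseries(frames, cutoff = 2)
  expect_equal(ts$nucleation, c(50, 50, 100))
  expect_equal(ts$event[3L], "coalescence")

  ## slow sustained growth is tagged as ripening
  sizes <- list(c(4, 3, 3), c(5, 3, 2), c(6, 2, 2), c(7, 2, 1), c(8, 1, 1))
  frames2 <- lapply(sizes, mk_frame)
  ts2 <- metrics_timeseries(frames2, cutoff = 2, ripening_window = 3L)
  expect_equal(tail(ts2$nucleation, 1L), 80)
  expect_true("ripening" %in% ts2$event)
})
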