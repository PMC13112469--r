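test_that("gallic unit is deterministic, neutral, and hydrogen-bond capable", {
  g1 <- build_gallic_unit()
  g2 <- build_gallic_unit()
  expect_identical(coords(g1), coords(g2))
  expect_equal(nrow(g1$atoms), 16)
  expect_equal(g1$net_charge, 0L)
  n_cap <- sum(g1$atoms$element == "O" &
                 g1$atoms$hbond_role %in% c("donor", "acceptor", "both"))
  expect_gte(n_cap, 4)
  expect_gte(min(dist(coords(g1))), 0.7)
})

test_that("oligomer stacks n clash-free units and buries interface area", {
  p9 <- build_pgal_oligomer(9)
  expect_equal(nrow(p9$atoms), 9 * 16)
  expect_equal(p9$net_charge, 0L)
  expect_gte(min(dist(coords(p9))), 0.7)
  p1 <- build_pgal_oligomer(1)
  expect_equal(coords(p1), coords(build_gallic_unit()), ignore_attr = TRUE)
  # stacking buries surface: SASA(2 units) < 2 x SASA(1 unit)
  s1 <- sasa(p1)$total
  s2 <- sasa(build_pgal_oligomer(2))$total
  expect_lt(s2, 2 * s1)
  expect_error(build_pgal_oligomer(0), "n_units")
})

test_that("histidine states carry the right charge and donor/acceptor pattern", {
  pr <- build_histidine("protonated")
  zw <- build_histidine("zwitterionic")
  expect_equal(pr$net_charge, 1L)
  expect_equal(zw$net_charge, 0L)
  expect_lt(abs(sum(pr$atoms$charge) - 1), 1e-6)
  expect_lt(abs(sum(zw$atoms$charge)), 1e-6)
  # same heavy-atom skeleton; they differ by the ring proton HE2
  heavy <- function(m) m$atoms[m$atoms$element != "H", ]
  expect_equal(heavy(pr)$name, heavy(zw)$name)
  expect_equal(as.matrix(heavy(pr)[, c("x", "y", "z")]),
               as.matrix(heavy(zw)[, c("x", "y", "z")]),
               ignore_attr = TRUE)
  expect_setdiff <- setdiff(pr$atoms$name, zw$atoms$name)
  expect_equal(expect_setdiff, "HE2")
  role <- function(m, a) m$atoms$hbond_role[m$atoms$name == a]
  expect_true(all(c(role(pr, "ND1"), role(pr, "NE2")) == "donor"))
  expect_equal(role(zw, "NE2"), "acceptor")
  expect_error(build_histidine("neutral"))
})

test_that("pose sampling fills the contact shell and reproduces under seed", {
  rec <- build_pgal_oligomer(3)
  lig <- build_histidine("zwitterionic")
  ps <- sample_poses(rec, lig, n_poses = 6, replicates = 3, seed = 7)
  expect_equal(nrow(ps$poses), 18)
  expect_true(all(ps$poses$min_dist >= ps$clash_min))
  expect_true(all(ps$poses$min_dist <= ps$contact_max))
  # recomputed closest approach agrees with the stored one
  for (i in c(1, 9, 18)) {
    posed <- apply_pose(ps$poses[i, ], lig)
    expect_equal(min_cross_dist_cpp(coords(rec), coords(posed)),
                 ps$poses$min_dist[i], tolerance = 1e-9)
  }
  ps2 <- sample_poses(rec, lig, n_poses = 6, replicates = 3, seed = 7)
  expect_identical(ps$poses, ps2$poses)
  ps3 <- sample_poses(rec, lig, n_poses = 6, replicates = 3, seed = 8)
  expect_false(identical(ps$poses, ps3$poses))
})

test_that("impossible clash constraints raise a sampling error", {
  rec <- build_gallic_unit()
  lig <- build_histidine("zwitterionic")
  expect_error(sample_poses(rec, lig, n_poses = 1, replicates = 1, seed = 1,
                            clash_min = 50))
})

test_that("pose constraints hold across seeds (property)", {
  rec <- build_pgal_oligomer(2)
  lig <- build_histidine("protonated")
  for (seed in c(11, 23, 101)) {
    ps <- sample_poses(rec, lig, n_poses = 4, replicates = 1, seed = seed)
    expect_true(all(ps$poses$min_dist >= 2.2 & ps$poses$min_dist <= 4.5))
    q <- as.matrix(ps$poses[, c("qw", "qx", "qy", "qz")])
    expect_equal(rowSums(q^2), rep(1, nrow(q)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("orientation sampling is rotation-uniform", {
  n <- 10000
  acc <- matrix(0, 3, 3)
  set.seed(42)
  for (i in seq_len(n)) acc <- acc + versor_to_matrix(random_versor())
  m <- acc / n
  # entries of a uniform rotation matrix have mean 0, variance 1/3
  expect_true(all(abs(m) < 3 * sqrt(1 / (3 * n))))
})

test_that("apply_pose is an exact rigid motion", {
  lig <- build_histidine("zwitterionic")
  pose <- list(pose_id = 1, replicate = 1, qw = 1, qx = 0, qy = 0, qz = 0,
               tx = 5, ty = -2, tz = 3)
  moved <- apply_pose(pose, lig)
  ctr <- colMeans(coords(lig))
  expect_equal(coords(moved),
               sweep(coords(lig), 2, ctr - c(5, -2, 3)),
               ignore_attr = TRUE)
  expect_equal(as.matrix(dist(coords(moved))), as.matrix(dist(coords(lig))),
               tolerance = 1e-12)
})

test_that("pose ensembles round-trip through the transform table", {
  rec <- build_pgal_oligomer(2)
  lig <- build_histidine("protonated")
  ps <- sample_poses(rec, lig, n_poses = 3, replicates = 1, seed = 5)
  tab <- withr::local_tempfile(fileext = ".tsv")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pose_set(ps, tab, pdb)
  back <- utils::read.table(tab, header = TRUE)
  expect_equal(back$qw, ps$poses$qw, tolerance = 1e-9)
  expect_equal(back$tx, ps$poses$tx, tolerance = 1e-9)
  expect_equal(sum(grepl("^MODEL", readLines(pdb))), 3)
})
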