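test_that("isolated sphere SASA matches 4*pi*(r+probe)^2", {
  a <- make_ion(0, c(0, 0, 0), radius = 1.9)
  s <- sasa(a, probe = 1.4)
  expect_equal(s$total, 4 * pi * 3.3^2, tolerance = 0.01)
  # additivity for non-overlapping spheres is exact
  two <- molecule("two", rbind(a$atoms,
                               make_ion(0, c(200, 0, 0), radius = 1.9)$atoms),
                  validate = FALSE)
  expect_equal(sasa(two, probe = 1.4)$total, 2 * s$total, tolerance = 1e-12)
})

test_that("a fully enclosed atom has zero accessible area", {
  shell_dirs <- golden_spiral_points(80)
  shell <- do.call(rbind, lapply(seq_len(80), function(i)
    make_polar_atom(paste0("S", i), "C", 2.4 * shell_dirs[i, ], "none")))
  shell$radius <- 1.3
  core <- make_polar_atom("CORE", "C", c(0, 0, 0), "none")
  core$radius <- 1.0
  m <- molecule("cage", rbind(core, shell), validate = FALSE)
  s <- sasa(m, probe = 1.4)
  expect_equal(s$per_atom[1], 0)
})

test_that("two overlapping spheres match the analytic lens formula", {
  a <- make_ion(0, c(0, 0, 0), radius = 1.9)
  b <- make_ion(0, c(3, 0, 0), radius = 1.9)
  m <- molecule("pair", rbind(a$atoms, b$atoms), validate = FALSE)
  s <- sasa(m, probe = 1.4, n_points = 3840)
  expect_equal(s$total, two_sphere_sasa(3.3, 3.0), tolerance = 0.01)
})

test_that("SASA result satisfies its bookkeeping invariants", {
  m <- build_histidine("zwitterionic")
  s <- sasa(m)
  expect_equal(s$total, sum(s$per_atom), tolerance = 1e-9)
  expect_true(all(s$per_atom >= 0))
  expect_true(all(s$per_atom <=
                    4 * pi * (m$atoms$radius + s$probe_radius)^2 + 1e-9))
  bad <- m
  bad$atoms$radius[2] <- 0
  expect_error(sasa(bad), "radius")
})

test_that("quadrature error shrinks monotonically toward a dense reference", {
  # per-atom RMS against a 100k-point reference: the per-atom errors decay
  # ~ n^(-3/4); totals benefit from cancellation and are less diagnostic
  mk <- function(seed) {
    set.seed(seed)
    xyz <- matrix(rnorm(60, sd = 2.5), ncol = 3)
    at <- do.call(rbind, lapply(seq_len(20), function(i)
      make_polar_atom(paste0("A", i), "C", xyz[i, ], "none")))
    at$radius <- runif(20, 1.2, 2.0)
    molecule("cluster", at, validate = FALSE)
  }
  ms <- lapply(c(3, 5, 7), mk)
  refs <- lapply(ms, function(m) sasa(m, n_points = 100000)$per_atom)
  errs <- sapply(c(240, 960, 3840), function(np)
    mean(mapply(function(m, r)
      sqrt(mean((sasa(m, n_points = np)$per_atom - r)^2)), ms, refs)))
  expect_true(all(diff(errs) < 0))
})

test_that("SASA is exactly translation-invariant and stable under rotation", {
  m <- build_histidine("protonated")
  s0 <- sasa(m)$total
  tr <- m
  tr$atoms[, c("x", "y", "z")] <- sweep(coords(m), 2, c(11.3, -4.2, 7.9), "+")
  expect_equal(sasa(tr)$total, s0, tolerance = 1e-12)
  th <- 0.83
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rx <- m
  rx$atoms[, c("x", "y", "z")] <- coords(m) %*% t(rot)
  # quadrature points are a fixed global set, so rotation agreement is at
  # the quadrature tolerance, not exact
  expect_equal(sasa(rx, n_points = 3840)$total, sasa(m, n_points = 3840)$total,
               tolerance = 0.005)
})

test_that("buried area on binding is negative for contacts, zero when apart", {
  rec <- build_pgal_oligomer(2)
  lig <- build_histidine("zwitterionic")
  ps <- sample_poses(rec, lig, n_poses = 5, replicates = 1, seed = 3)
  for (i in seq_len(5)) {
    posed <- apply_pose(ps$poses[i, ], lig)
    expect_lt(delta_sasa(rec, posed), 0)
  }
  far <- lig
  far$atoms[, c("x", "y", "z")] <- sweep(coords(lig), 2, c(300, 0, 0), "+")
  expect_equal(delta_sasa(rec, far), 0, tolerance = 1e-9)
})

test_that("the non-polar term converts gamma*dSASA from cal to kJ", {
  expect_equal(nonpolar_energy(-239.0, gamma = 5), -4.99988,
               tolerance = 1e-6)
  expect_equal(nonpolar_energy(0), 0)
  expect_equal(nonpolar_energy(-100, gamma = 5), -5 * 100 * 4.184 / 1000,
               tolerance = 1e-12)
  expect_error(nonpolar_energy(-10, gamma = 0))
})
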