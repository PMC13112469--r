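ke <- energy_constants()$coulomb

test_that("pairwise Coulomb energies match the closed form", {
  a <- make_ion(1, c(0, 0, 0))
  b <- make_ion(1, c(1, 0, 0))
  expect_equal(coulomb_energy(a, eps = 1, other = b), ke, tolerance = 1e-10)
  expect_equal(coulomb_energy(a, eps = 3, other = b), ke / 3,
               tolerance = 1e-10)
  expect_equal(coulomb_energy(a, eps = 1), 0)   # single atom
  # intra-molecular sum over three charges, brute force oracle
  at <- rbind(make_ion(0.5, c(0, 0, 0))$atoms,
              make_ion(-0.3, c(2, 0, 0))$atoms,
              make_ion(0.8, c(0, 3, 0))$atoms)
  m <- molecule("tri", at, validate = FALSE)
  brute <- ke / 2 * (0.5 * -0.3 / 2 + 0.5 * 0.8 / 3 +
                       -0.3 * 0.8 / sqrt(13))
  expect_equal(coulomb_energy(m, eps = 2), brute, tolerance = 1e-10)
  # coincident charges are a singularity
  cl <- make_ion(1, c(0, 0, 0))
  expect_error(coulomb_energy(cl, eps = 1, other = make_ion(1, c(0, 0, 0))),
               "singular")
})

test_that("zero-charge molecules have zero potential and energy", {
  n <- make_ion(0, c(0, 0, 0))
  res <- solve_poisson(n, diel = dielectric_model(), spacing = 1,
                       padding = 5)
  expect_equal(res$grid_energy, 0)
  expect_true(all(res$phi == 0))
  expect_equal(as.numeric(solvation_energy(n, spacing = 1, padding = 5)), 0)
})

test_that("finite-difference solvation approaches the Born closed form", {
  ion <- make_ion(1, c(0, 0, 0), radius = 2)
  diel <- dielectric_model(eps_solvent = 78, eps_solute = 1)
  errs <- sapply(c(1.0, 0.5, 0.25), function(h) {
    e <- as.numeric(solvation_energy(ion, diel, spacing = h, padding = 5,
                                     focus = TRUE))
    abs(e - born_energy(2, 1, 78))
  })
  expect_true(all(diff(errs) < 0))         # monotone error decay
  expect_lt(errs[3] / abs(born_energy(2, 1, 78)), 0.05)
  # generalized Born with the study dielectrics 3 -> 78
  e3 <- as.numeric(solvation_energy(ion, dielectric_model(78, 3),
                                    spacing = 0.25, padding = 5,
                                    focus = TRUE))
  expect_equal(e3, born_energy(2, 3, 78), tolerance = 0.05)
})

test_that("potentials superpose in a homogeneous medium", {
  a <- make_ion(1, c(-1.5, 0, 0))
  b <- make_ion(-0.6, c(1.5, 0, 0))
  both <- molecule("pair", rbind(a$atoms, b$atoms), validate = FALSE)
  diel <- dielectric_model(eps_solvent = 78, eps_solute = 2)
  grid <- make_grid(both, spacing = 0.5, padding = 5)
  # eps_out = eps_solute makes the medium uniform
  sol_ab <- solve_poisson(both, grid, diel, eps_out = 2, tol = 1e-9)
  sol_a <- solve_poisson(a, grid, diel, eps_out = 2, tol = 1e-9)
  sol_b <- solve_poisson(b, grid, diel, eps_out = 2, tol = 1e-9)
  expect_equal(sol_ab$phi, sol_a$phi + sol_b$phi, tolerance = 1e-6)
})

test_that("solvation energy is invariant under lattice-commensurate translation", {
  ion <- make_ion(1, c(0.3, -0.2, 0.7), radius = 2)
  diel <- dielectric_model(78, 3)
  e0 <- as.numeric(solvation_energy(ion, diel, spacing = 0.5, padding = 5))
  moved <- ion
  moved$atoms[, c("x", "y", "z")] <-
    sweep(coords(ion), 2, c(3.5, -2.0, 1.5), "+")
  e1 <- as.numeric(solvation_energy(moved, diel, spacing = 0.5,
                                    padding = 5))
  expect_equal(e1, e0, tolerance = 1e-6)
})

test_that("binding components: oracle ion pair, symmetry and separated limit", {
  cat_ <- make_ion(1, c(0, 0, 0), id = "cation")
  ani <- make_ion(-1, c(5, 0, 0), id = "anion")
  diel <- dielectric_model(78, 3)
  ec <- elec_binding_components(cat_, ani, diel, spacing = 0.5,
                                padding = 5, focus = TRUE)
  expect_equal(ec$dG_coul, -ke / (3 * 5), tolerance = 1e-10)
  expect_gt(ec$dG_solv, 0)                 # desolvation penalty
  # screened limit: dG_solv + dG_coul ~ ke/(78 r) attraction
  expect_equal(ec$dG_solv + ec$dG_coul, -ke / (78 * 5), tolerance = 2)
  # swapping receptor/ligand labels changes nothing
  ec_sw <- elec_binding_components(ani, cat_, diel, spacing = 0.5,
                                   padding = 5, focus = TRUE)
  expect_equal(ec_sw$dG_solv, ec$dG_solv, tolerance = 1e-9)
  expect_equal(ec_sw$dG_coul, ec$dG_coul, tolerance = 1e-12)
  # non-interacting limit: both components decay to ~0
  far <- make_ion(-1, c(200, 0, 0), id = "anion")
  ec_far <- elec_binding_components(cat_, far, diel, spacing = 1,
                                    padding = 5)
  expect_lt(abs(ec_far$dG_coul), 3)
  expect_lt(abs(ec_far$dG_solv), 3)
  expect_lt(abs(ec_far$dG_solv + ec_far$dG_coul), 0.5)
})

test_that("dielectric model rejects unphysical settings", {
  expect_error(dielectric_model(eps_solvent = 2, eps_solute = 3))
  expect_error(dielectric_model(eps_solvent = 78, eps_solute = 0.5))
  expect_error(dielectric_model(ionic_strength = -1))
})

test_that("grids enclose the solute with padding and minimum dimensions", {
  ion <- make_ion(1, c(0, 0, 0), radius = 2)
  g <- make_grid(ion, spacing = 1, padding = 5)
  expect_true(all(g$dims >= 33))
  top <- g$origin + (g$dims - 1) * g$spacing
  expect_true(all(g$origin <= -7) && all(top >= 7))
  expect_true(all(abs(g$origin / g$spacing -
                        round(g$origin / g$spacing)) < 1e-9))
  expect_error(make_grid(ion, spacing = -1), "spacing")
})

test_that("the potential field can be dumped in OpenDX format", {
  ion <- make_ion(1, c(0, 0, 0))
  res <- solve_poisson(ion, spacing = 1, padding = 5)
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(res, path)
  lines <- readLines(path)
  expect_true(any(grepl("gridpositions counts", lines)))
  n_declared <- as.integer(sub(".*items (\\d+) data.*", "\\1",
                               grep("items", lines, value = TRUE)))
  expect_equal(n_declared, prod(res$grid$dims))
})
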