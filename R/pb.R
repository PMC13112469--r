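#' Dielectric model for implicit-solvent electrostatics
#'
#' Defaults follow the two-dielectric description of the PGAL-histidine
#' system: water at 78 and the polymer interior at 3.0 (polyimide-like),
#' zero added salt, 298.15 K.
#'
#' @param eps_solvent Solvent dielectric constant (> `eps_solute`).
#' @param eps_solute Solute-interior dielectric constant (>= 1).
#' @param temperature Kelvin.
#' @param ionic_strength mol/L; 0 gives the pure Poisson equation.  A
#'   positive value applies Debye screening to the boundary condition
#'   (linearized treatment).
#' @return Object of class `dielectric_model`.
#' @export
dielectric_model <- function(eps_solvent = 78, eps_solute = 3.0,
                             temperature = 298.15, ionic_strength = 0) {
  if (!(eps_solvent > eps_solute && eps_solute >= 1))
    stop("require eps_solvent > eps_solute >= 1")
  if (ionic_strength < 0) stop("ionic_strength must be >= 0")
  structure(list(eps_solvent = eps_solvent, eps_solute = eps_solute,
                 temperature = temperature, ionic_strength = ionic_strength),
            class = "dielectric_model")
}

#' Finite-difference grid specification
#'
#' Builds a cubic-spacing grid box enclosing the molecule plus `padding` on
#' every side, with at least 33 nodes per axis.  The origin snaps to
#' multiples of the spacing so that a species held at fixed absolute
#' coordinates keeps the same registration against the nodes whether it is
#' gridded alone or as part of a complex — which is what lets the grid
#' self-energies cancel when solvation energies are differenced.
#'
#' @param mol A [molecule()] (radii assigned).
#' @param spacing Grid spacing h, Å.
#' @param padding Clearance between the solute's spheres and the box, Å
#'   (>= 5 recommended).
#' @param min_dim Minimum nodes per axis.
#' @return Object of class `grid_spec`: `origin`, `spacing`, `dims`.
#' @export
make_grid <- function(mol, spacing = 0.5, padding = 6, min_dim = 33) {
  stopifnot(spacing > 0, padding >= 0)
  xyz <- coords(mol)
  r <- mol$atoms$radius
  if (anyNA(r)) stop("radii must be assigned before gridding")
  lo <- apply(xyz - r, 2, min) - padding
  hi <- apply(xyz + r, 2, max) + padding
  origin <- floor(lo / spacing) * spacing
  dims <- ceiling((hi - origin) / spacing) + 1
  grow <- pmax(0, min_dim - dims)
  # grow symmetrically (in whole nodes) to reach the minimum dimension
  origin <- origin - ceiling(grow / 2) * spacing
  dims <- dims + ceiling(grow / 2) + floor(grow / 2)
  dims <- pmax(dims, min_dim)
  structure(list(origin = origin, spacing = spacing,
                 dims = as.integer(dims)), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d nodes, h = %.3f A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, x$origin[1],
              x$origin[2], x$origin[3]))
  invisible(x)
}

# Trilinear spread of atomic charges onto grid nodes.
spread_charges <- function(grid, xyz, q) {
  dims <- grid$dims; h <- grid$spacing; org <- grid$origin
  rho <- numeric(prod(dims))
  for (a in seq_len(nrow(xyz))) {
    if (q[a] == 0) next
    f <- (xyz[a, ] - org) / h
    i0 <- floor(f)
    w <- f - i0
    if (any(i0 < 0) || any(i0 + 1 > dims - 1))
      stop("atom outside grid box")
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) w[1] else 1 - w[1]) *
            (if (dy) w[2] else 1 - w[2]) *
            (if (dz) w[3] else 1 - w[3])
      idx <- (i0[1] + dx) + dims[1] * ((i0[2] + dy) + dims[2] * (i0[3] + dz))
      rho[idx + 1] <- rho[idx + 1] + q[a] * wt
    }
  }
  rho
}

# Trilinear interpolation of the node field at atom positions.
interp_field <- function(grid, phi, xyz) {
  dims <- grid$dims; h <- grid$spacing; org <- grid$origin
  out <- numeric(nrow(xyz))
  for (a in seq_len(nrow(xyz))) {
    f <- (xyz[a, ] - org) / h
    i0 <- pmin(pmax(floor(f), 0), dims - 2)
    w <- f - i0
    s <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) w[1] else 1 - w[1]) *
            (if (dy) w[2] else 1 - w[2]) *
            (if (dz) w[3] else 1 - w[3])
      idx <- (i0[1] + dx) + dims[1] * ((i0[2] + dy) + dims[2] * (i0[3] + dz))
      s <- s + wt * phi[idx + 1]
    }
    out[a] <- s
  }
  out
}

#' Solve the Poisson equation for a molecule on a grid
#'
#' Finite-difference solution of \eqn{\nabla\cdot(\epsilon\nabla\phi) =
#' -4\pi k_e \rho} with the solute dielectric inside the atoms' van der
#' Waals spheres and `eps_out` outside (harmonic dielectric averaging on
#' grid edges), analytic Coulomb Dirichlet values on the box faces, and
#' successive over-relaxation.  With `focus = TRUE` a coarse large-box pass
#' (4x spacing, extra padding) supplies the fine-box boundary values.
#' Returns the charge-potential grid energy \eqn{\tfrac12\sum_i q_i
#' \phi(r_i)}; this contains the grid self-energy and is only meaningful in
#' differences taken on an identical grid, which is how
#' [solvation_energy()] uses it.
#'
#' @param mol A [molecule()] with charges and radii assigned.
#' @param grid A [make_grid()] spec; built from `mol` if `NULL`.
#' @param diel A [dielectric_model()]; `eps_solute` fills the atom interior.
#' @param eps_out Dielectric outside the solute region.
#' @param focus Use a two-level focusing pass.
#' @param tol Relative residual for convergence.
#' @param maxit Maximum SOR sweeps.
#' @param spacing,padding Used when `grid` is `NULL`.
#' @return Object of class `pb_result`: `grid_energy` (kJ/mol), `phi`
#'   (potential field, kJ/mol/e), `grid`, `converged`, `iterations`,
#'   `residual`.
#' @export
solve_poisson <- function(mol, grid = NULL, diel = dielectric_model(),
                          eps_out = diel$eps_solvent, focus = FALSE,
                          tol = 1e-6, maxit = 20000, spacing = 0.5,
                          padding = 6) {
  if (is.null(grid)) grid <- make_grid(mol, spacing, padding)
  xyz <- coords(mol)
  q <- mol$atoms$charge
  r <- mol$atoms$radius
  if (anyNA(q) || anyNA(r)) stop("charges and radii must be assigned")
  if (all(q == 0)) {
    phi <- numeric(prod(grid$dims))
    return(structure(list(grid_energy = 0, phi = phi, grid = grid,
                          converged = TRUE, iterations = 0L, residual = 0),
                     class = "pb_result"))
  }
  run_level <- function(grid, phi_init = NULL) {
    dims <- grid$dims; h <- grid$spacing
    inside <- grid_inside_mask_cpp(dims, grid$origin, h, xyz, r)
    eps_node <- ifelse(inside, diel$eps_solute, eps_out)
    rho <- spread_charges(grid, xyz, q)
    # analytic Coulomb field as initial guess; its box-face values are the
    # Dirichlet boundary condition (faces are never updated by the solver)
    phi <- if (is.null(phi_init))
      coulomb_field_cpp(dims, grid$origin, h, xyz, q, eps_out)
    else phi_init
    nmax <- max(dims)
    omega <- 2 / (1 + sin(pi / nmax))
    sor_poisson_cpp(dims, eps_node, rho, phi, h, omega, tol, maxit)
  }
  if (focus) {
    coarse <- make_grid(mol, spacing = grid$spacing * 4,
                        padding = .grid_padding(mol, grid) + 12)
    sol_c <- run_level(coarse)
    # fine boundary from coarse solution
    dims <- grid$dims; h <- grid$spacing
    phi0 <- coulomb_field_cpp(dims, grid$origin, h, xyz, q, eps_out)
    bidx <- boundary_indices(dims)
    bxyz <- node_xyz(grid, bidx)
    phi0[bidx + 1] <- interp_field(coarse, sol_c$phi, bxyz)
    sol <- run_level_with_init(grid, phi0, xyz, q, r, diel, eps_out, tol,
                               maxit)
  } else {
    sol <- run_level(grid)
  }
  phi <- sol$phi
  e <- 0.5 * sum(q * interp_field(grid, phi, xyz))
  structure(list(grid_energy = e, phi = phi, grid = grid,
                 converged = sol$converged, iterations = sol$iterations,
                 residual = sol$residual),
            class = "pb_result")
}

# SOR run with a supplied initial/boundary field (focusing fine pass).
run_level_with_init <- function(grid, phi0, xyz, q, r, diel, eps_out, tol,
                                maxit) {
  dims <- grid$dims; h <- grid$spacing
  inside <- grid_inside_mask_cpp(dims, grid$origin, h, xyz, r)
  eps_node <- ifelse(inside, diel$eps_solute, eps_out)
  rho <- spread_charges(grid, xyz, q)
  omega <- 2 / (1 + sin(pi / max(dims)))
  sor_poisson_cpp(dims, eps_node, rho, phi0, h, omega, tol, maxit)
}

# linear indices (0-based) of all boundary nodes
boundary_indices <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  i <- rep(0:(nx - 1), times = ny * nz)
  j <- rep(rep(0:(ny - 1), each = nx), times = nz)
  k <- rep(0:(nz - 1), each = nx * ny)
  on_b <- i == 0 | i == nx - 1 | j == 0 | j == ny - 1 | k == 0 | k == nz - 1
  (i + nx * (j + ny * k))[on_b]
}

node_xyz <- function(grid, idx0) {
  nx <- grid$dims[1]; ny <- grid$dims[2]
  i <- idx0 %% nx
  j <- (idx0 %/% nx) %% ny
  k <- idx0 %/% (nx * ny)
  cbind(grid$origin[1] + i * grid$spacing,
        grid$origin[2] + j * grid$spacing,
        grid$origin[3] + k * grid$spacing)
}

# effective padding a grid leaves around the molecule (smallest clearance)
.grid_padding <- function(mol, grid) {
  xyz <- coords(mol); r <- mol$atoms$radius
  lo <- apply(xyz - r, 2, min)
  hi <- apply(xyz + r, 2, max)
  top <- grid$origin + (grid$dims - 1) * grid$spacing
  max(2, min(c(lo - grid$origin, top - hi)))
}

#' Electrostatic solvation energy by same-grid differencing
#'
#' Two Poisson solves on the identical grid — exterior dielectric set to
#' the solvent and to the solute value — differenced so the grid
#' self-energy cancels: \eqn{\Delta G_{solv} = G(\epsilon_{out} =
#' \epsilon_{solvent}) - G(\epsilon_{out} = \epsilon_{solute})}.
#'
#' @inheritParams solve_poisson
#' @return Solvation energy in kJ/mol (attribute `pb` holds the two
#'   [solve_poisson()] results).
#' @export
solvation_energy <- function(mol, diel = dielectric_model(), spacing = 0.5,
                             padding = 6, grid = NULL, focus = FALSE,
                             tol = 1e-6, maxit = 20000) {
  if (is.null(grid)) grid <- make_grid(mol, spacing, padding)
  a <- solve_poisson(mol, grid, diel, eps_out = diel$eps_solvent,
                     focus = focus, tol = tol, maxit = maxit)
  b <- solve_poisson(mol, grid, diel, eps_out = diel$eps_solute,
                     focus = focus, tol = tol, maxit = maxit)
  if (!a$converged || !b$converged)
    stop("Poisson solver did not converge; refusing to report a solvation energy")
  structure(a$grid_energy - b$grid_energy, pb = list(solvent = a, ref = b))
}

#' Pairwise Coulomb energy
#'
#' \eqn{\sum_{i<j} k_e q_i q_j / (\epsilon r_{ij})} within one molecule, or
#' the intermolecular cross sum when `other` is given (the binding Coulomb
#' term of a rigid complex, since intramolecular sums cancel on binding).
#'
#' @param mol A [molecule()] with charges assigned.
#' @param eps Uniform dielectric constant (>= 1).
#' @param other Optional second [molecule()]: compute the intermolecular
#'   cross term instead.
#' @return Energy in kJ/mol.
#' @export
coulomb_energy <- function(mol, eps = 1, other = NULL) {
  stopifnot(eps >= 1)
  q1 <- mol$atoms$charge
  if (anyNA(q1)) stop("charges must be assigned")
  x1 <- coords(mol)
  if (is.null(other)) {
    if (nrow(x1) < 2) return(0)
    d <- as.matrix(stats::dist(x1))
    qq <- outer(q1, q1)
    if (any(d[upper.tri(d)] < 1e-6 & abs(qq[upper.tri(qq)]) > 0))
      stop("coincident charged atoms: Coulomb singularity")
    diag(d) <- Inf
    return(.ke_kjmol_ang / eps * sum(qq / d) / 2)
  }
  q2 <- other$atoms$charge
  if (anyNA(q2)) stop("charges must be assigned")
  x2 <- coords(other)
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
  d <- sqrt(pmax(d2, 0))
  qq <- outer(q1, q2)
  if (any(d < 1e-6 & abs(qq) > 0))
    stop("coincident charged atoms: Coulomb singularity")
  d[d < 1e-12] <- Inf
  .ke_kjmol_ang / eps * sum(qq / d)
}

#' Electrostatic binding components of a posed complex
#'
#' \eqn{\Delta G_{solv}} is the solvation energy of the complex minus those
#' of the free receptor and ligand, all computed with the same spacing,
#' padding and dielectric model; \eqn{\Delta G_{coul}} is the
#' intermolecular Coulomb sum at the solute dielectric.  Free-species
#' solvation energies can be passed in (`ref`) so pose ensembles do not
#' recompute them.
#'
#' @param receptor,ligand [molecule()] objects; `ligand` already posed.
#' @param diel A [dielectric_model()].
#' @param spacing,padding Grid parameters shared by all three solves.
#' @param focus,tol,maxit Passed to [solvation_energy()].
#' @param ref Optional list with `receptor` and `ligand` solvation energies
#'   (kJ/mol) precomputed at identical settings.
#' @return List with `dG_solv` and `dG_coul` (kJ/mol).
#' @export
elec_binding_components <- function(receptor, ligand,
                                    diel = dielectric_model(),
                                    spacing = 0.5, padding = 6,
                                    focus = FALSE, tol = 1e-6,
                                    maxit = 20000, ref = NULL) {
  cmplx <- combine_molecules(receptor, ligand)
  g_c <- solvation_energy(cmplx, diel, spacing, padding, focus = focus,
                          tol = tol, maxit = maxit)
  g_r <- if (!is.null(ref)) ref$receptor else
    solvation_energy(receptor, diel, spacing, padding, focus = focus,
                     tol = tol, maxit = maxit)
  g_l <- if (!is.null(ref)) ref$ligand else
    solvation_energy(ligand, diel, spacing, padding, focus = focus,
                     tol = tol, maxit = maxit)
  list(dG_solv = as.numeric(g_c) - as.numeric(g_r) - as.numeric(g_l),
       dG_coul = coulomb_energy(receptor, eps = diel$eps_solute,
                                other = ligand))
}

#' Write a scalar field in OpenDX format
#'
#' Dumps the potential of a [solve_poisson()] result as an OpenDX
#' regular-grid file for visual inspection in standard viewers.
#'
#' @param pb A `pb_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(pb, path) {
  g <- pb$grid
  n <- prod(g$dims)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field written by polybind",
    sprintf("object 1 class gridpositions counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("origin %.6f %.6f %.6f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", g$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", g$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            n)), con)
  # DX stores with z fastest; phi is x-fastest
  arr <- array(pb$phi, g$dims)
  vals <- as.vector(aperm(arr, c(3, 2, 1)))
  writeLines(apply(matrix(c(sprintf("%.6e", vals),
                            rep("", (3 - n %% 3) %% 3)), nrow = 3), 2,
                   paste, collapse = " "), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
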