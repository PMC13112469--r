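#' Deterministic quasi-uniform sphere point set (golden spiral)
#'
#' Fixed Fibonacci-lattice unit vectors used as the Shrake-Rupley
#' quadrature; deterministic, so SASA values are bit-reproducible.
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n = 960) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * k
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible area from spherical point quadrature on each atom's
#' expanded sphere (radius + probe) against all neighbouring expanded
#' spheres, with neighbour culling at \eqn{r_i + r_j + 2\,probe}.
#'
#' @param mol A [molecule()] with radii assigned.
#' @param probe Probe radius, Å (water: 1.4).
#' @param n_points Quadrature points per atom.
#' @return Object of class `sasa_result`: `total` (Å²), `per_atom`,
#'   `probe_radius`, `n_points`.
#' @export
sasa <- function(mol, probe = 1.4, n_points = 960) {
  stopifnot(probe >= 0, n_points >= 12)
  r <- mol$atoms$radius
  if (anyNA(r) || any(r <= 0))
    stop("all atoms need a positive radius for SASA")
  per <- sasa_per_atom_cpp(coords(mol), r, probe,
                           golden_spiral_points(n_points))
  structure(list(total = sum(per), per_atom = as.numeric(per),
                 probe_radius = probe, n_points = as.integer(n_points)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.2f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$per_atom), x$probe_radius, x$n_points))
  invisible(x)
}

#' Buried surface area upon complex formation
#'
#' \eqn{\Delta SASA = SASA(complex) - SASA(receptor) - SASA(ligand)} with
#' the same probe and quadrature for all three species; non-positive for
#' any contacting pose and zero for separated species.
#'
#' @param receptor,ligand [molecule()] objects; `ligand` already posed.
#' @param probe Probe radius, Å.
#' @param n_points Quadrature points per atom.
#' @return ΔSASA in Å².
#' @export
delta_sasa <- function(receptor, ligand, probe = 1.4, n_points = 960) {
  cmplx <- combine_molecules(receptor, ligand)
  sasa(cmplx, probe, n_points)$total -
    sasa(receptor, probe, n_points)$total -
    sasa(ligand, probe, n_points)$total
}

#' Non-polar (hydrophobic) binding energy
#'
#' \eqn{\Delta G_{non-elec} = \gamma \cdot \Delta SASA}, with the
#' interfacial tension coefficient \eqn{\gamma} given in
#' cal mol\eqn{^{-1}} Å\eqn{^{-2}} (default 5) and the result converted to
#' kJ/mol.  No offset constant is applied.
#'
#' @param delta_area ΔSASA in Å².
#' @param gamma Interfacial tension coefficient, cal mol⁻¹ Å⁻².
#' @return Energy in kJ/mol (same sign as `delta_area`).
#' @export
nonpolar_energy <- function(delta_area, gamma = 5) {
  stopifnot(gamma > 0)
  gamma * delta_area * .cal_to_kj
}
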