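#' Binding free-energy decomposition
#'
#' The per-pose unit of analysis: solvation, Coulomb and non-polar
#' components with their sum, \eqn{\Delta G_b = \Delta G_{solv} + \Delta
#' G_{coul} + \Delta G_{non-elec}}.  The identity is maintained at
#' construction: `dG_b` is always the exact sum of the three components.
#'
#' @param dG_solv,dG_coul,dG_nonelec Components in kJ/mol.
#' @return Object of class `energy_decomposition` with fields `dG_solv`,
#'   `dG_coul`, `dG_nonelec`, `dG_b`.
#' @export
#' @examples
#' energy_decomposition(46, -96, -5.0)$dG_b   # -55
energy_decomposition <- function(dG_solv, dG_coul, dG_nonelec) {
  stopifnot(is.finite(dG_solv), is.finite(dG_coul), is.finite(dG_nonelec))
  structure(list(dG_solv = dG_solv, dG_coul = dG_coul,
                 dG_nonelec = dG_nonelec,
                 dG_b = dG_solv + dG_coul + dG_nonelec),
            class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("dG_solv %8.2f  dG_coul %8.2f  dG_nonelec %8.2f  ->  dG_b %8.2f kJ/mol\n",
              x$dG_solv, x$dG_coul, x$dG_nonelec, x$dG_b))
  invisible(x)
}

#' Detect intermolecular hydrogen bonds
#'
#' Distance-based criterion on heavy atoms: every intermolecular pair in
#' which one atom can donate (`hbond_role` of `"donor"` or `"both"`) and
#' the other can accept, at a donor-acceptor distance at or below
#' `cutoff`.  No angle term is applied (the templates carry polar
#' hydrogens only).  A pair capable of bonding in both directions is
#' reported once.
#'
#' @param receptor,ligand [molecule()] objects; `ligand` already posed.
#' @param cutoff Heavy-atom donor-acceptor distance cutoff, Å.
#' @return Data frame sorted by distance: `donor`, `acceptor`,
#'   `donor_mol`, `acceptor_mol`, `distance`.
#' @export
detect_hbonds <- function(receptor, ligand, cutoff = 3.35) {
  pairs_dir <- function(a, b, a_lab, b_lab) {
    don <- which(a$atoms$hbond_role %in% c("donor", "both") &
                   a$atoms$element != "H")
    acc <- which(b$atoms$hbond_role %in% c("acceptor", "both") &
                   b$atoms$element != "H")
    if (!length(don) || !length(acc)) return(NULL)
    xa <- coords(a)[don, , drop = FALSE]
    xb <- coords(b)[acc, , drop = FALSE]
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(
      donor = paste0(a$atoms$resname[don[hit[, 1]]],
                     a$atoms$resid[don[hit[, 1]]], ":",
                     a$atoms$name[don[hit[, 1]]]),
      acceptor = paste0(b$atoms$resname[acc[hit[, 2]]],
                        b$atoms$resid[acc[hit[, 2]]], ":",
                        b$atoms$name[acc[hit[, 2]]]),
      donor_mol = a_lab, acceptor_mol = b_lab,
      distance = sqrt(pmax(d2[hit], 0)), stringsAsFactors = FALSE)
  }
  out <- rbind(pairs_dir(receptor, ligand, "receptor", "ligand"),
               pairs_dir(ligand, receptor, "ligand", "receptor"))
  if (is.null(out))
    return(data.frame(donor = character(), acceptor = character(),
                      donor_mol = character(), acceptor_mol = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  # collapse pairs hit in both directions onto one row
  key <- ifelse(out$donor_mol == "receptor",
                paste(out$donor, out$acceptor),
                paste(out$acceptor, out$donor))
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$distance, out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score one rigid-body pose
#'
#' Assembles the full decomposition for a pose: Poisson solvation and
#' Coulomb terms from [elec_binding_components()], the non-polar term from
#' [nonpolar_energy()] applied to [delta_sasa()], and the hydrogen-bond
#' table.  A pose whose Poisson solve fails to converge is returned with
#' `scored = FALSE` and is excluded from ranking.
#'
#' @param pose One row of a pose table (see [sample_poses()]).
#' @param receptor,ligand [molecule()] objects (ligand in its reference
#'   frame; the pose transform is applied here).
#' @param diel A [dielectric_model()].
#' @param spacing,padding Grid parameters, Å.
#' @param probe SASA probe radius, Å.
#' @param gamma Interfacial tension coefficient, cal mol⁻¹ Å⁻².
#' @param n_points SASA quadrature points.
#' @param hbond_cutoff Donor-acceptor distance cutoff, Å.
#' @param ref Optional precomputed free-species reference: list with
#'   `solv_receptor` (kJ/mol), `sasa_receptor`, `sasa_ligand` (Å²).  The
#'   free ligand's solvation energy is always recomputed on the posed
#'   coordinates: grid origins snap to the spacing lattice, so posed-frame
#'   references share the complex run's node registration and the grid
#'   self-energy cancels exactly in the difference.
#' @param focus,tol,maxit Poisson solver controls.
#' @return Object of class `pose_score`: `pose_id`, `replicate`,
#'   `decomposition`, `hbonds`, `scored`, `note`.
#' @export
score_pose <- function(pose, receptor, ligand, diel = dielectric_model(),
                       spacing = 0.5, padding = 6, probe = 1.4, gamma = 5,
                       n_points = 960, hbond_cutoff = 3.35, ref = NULL,
                       focus = FALSE, tol = 1e-6, maxit = 20000) {
  posed <- apply_pose(pose, ligand)
  if (is.null(ref)) {
    ref <- list(
      solv_receptor = as.numeric(solvation_energy(receptor, diel, spacing,
                                                  padding, focus = focus,
                                                  tol = tol, maxit = maxit)),
      sasa_receptor = sasa(receptor, probe, n_points)$total,
      sasa_ligand = sasa(ligand, probe, n_points)$total)
  }
  cmplx <- combine_molecules(receptor, posed)
  res <- tryCatch({
    g_c <- solvation_energy(cmplx, diel, spacing, padding, focus = focus,
                            tol = tol, maxit = maxit)
    g_l <- solvation_energy(posed, diel, spacing, padding, focus = focus,
                            tol = tol, maxit = maxit)
    dG_solv <- as.numeric(g_c) - ref$solv_receptor - as.numeric(g_l)
    dG_coul <- coulomb_energy(receptor, eps = diel$eps_solute, other = posed)
    darea <- sasa(cmplx, probe, n_points)$total - ref$sasa_receptor -
      ref$sasa_ligand
    list(dec = energy_decomposition(dG_solv, dG_coul,
                                    nonpolar_energy(darea, gamma)),
         note = "")
  }, error = function(e) list(dec = NULL, note = conditionMessage(e)))
  structure(list(pose_id = pose$pose_id, replicate = pose$replicate,
                 decomposition = res$dec,
                 hbonds = detect_hbonds(receptor, posed,
                                        cutoff = hbond_cutoff),
                 scored = !is.null(res$dec), note = res$note),
            class = "pose_score")
}

#' Rank scored poses by binding free energy
#'
#' Ascending by \eqn{\Delta G_b} (most favorable first); ties broken by
#' replicate then pose id.  Unscored poses are dropped.  The ordering is
#' total, so permuting the input leaves the output unchanged.
#'
#' @param scores List of `pose_score` objects.
#' @return List with `ranking` (data frame of `pose_id`, `replicate`,
#'   `dG_solv`, `dG_coul`, `dG_nonelec`, `dG_b`), `best` (the top
#'   `pose_score`), and `n_unscored`.
#' @export
rank_poses <- function(scores) {
  scored <- Filter(function(s) isTRUE(s$scored), scores)
  if (!length(scored)) stop("no scored poses to rank")
  tab <- do.call(rbind, lapply(scored, function(s) data.frame(
    pose_id = s$pose_id, replicate = s$replicate,
    dG_solv = s$decomposition$dG_solv, dG_coul = s$decomposition$dG_coul,
    dG_nonelec = s$decomposition$dG_nonelec, dG_b = s$decomposition$dG_b)))
  ord <- order(tab$dG_b, tab$replicate, tab$pose_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(ranking = tab, best = scored[[ord[1]]],
       n_unscored = length(scores) - length(scored))
}

#' Interaction report for the best-ranked complex
#'
#' Deterministic structured text: the four energy lines (two significant
#' figures, full precision retained in the objects), the hydrogen-bond
#' table and pose provenance.
#'
#' @param best A `pose_score` (typically `rank_poses(...)$best`).
#' @param label Report heading.
#' @return Character vector of report lines.
#' @export
interaction_report <- function(best, label = "best complex") {
  if (!isTRUE(best$scored)) stop("cannot report an unscored pose")
  d <- best$decomposition
  fmt <- function(x) format(signif(x, 2))
  lines <- c(
    sprintf("== interaction report: %s ==", label),
    sprintf("pose %d (replicate %d)", best$pose_id, best$replicate),
    "",
    sprintf("dG_solv     %8s kJ/mol", fmt(d$dG_solv)),
    sprintf("dG_coul     %8s kJ/mol", fmt(d$dG_coul)),
    sprintf("dG_non-elec %8s kJ/mol", fmt(d$dG_nonelec)),
    sprintf("dG_b        %8s kJ/mol", fmt(d$dG_b)),
    "",
    sprintf("hydrogen bonds (heavy-atom cutoff): %d", nrow(best$hbonds)))
  if (nrow(best$hbonds)) {
    hb <- best$hbonds
    lines <- c(lines, sprintf("  %-16s %-16s %6.2f A", hb$donor,
                              hb$acceptor, hb$distance))
  }
  lines
}
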