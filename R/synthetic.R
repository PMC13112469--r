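#' Idealized gallic-acid unit
#'
#' Planar 3,4,5-trihydroxybenzoic-acid unit with explicit polar hydrogens
#' (carboxyl OH and the three ring hydroxyls); nonpolar ring hydrogens are
#' folded into the heavy-atom radii.  Charges, radii and hydrogen-bond
#' roles come from the bundled `GAL` template, whose partial charges sum to
#' the unit's formal charge of 0 (fully protonated).  Deterministic: two
#' calls give identical coordinates.
#'
#' @param resid Residue number to stamp on the atoms.
#' @param table Charge/radius template table.
#' @return A [molecule()] with net charge 0.
#' @export
build_gallic_unit <- function(resid = 1, table = default_charge_table()) {
  deg <- pi / 180
  ring_r <- 1.39            # benzene circumradius = bond length, Angstrom
  ring_th <- (0:5) * 60 * deg
  ring <- cbind(ring_r * cos(ring_th), ring_r * sin(ring_th), 0)
  c7 <- c(ring_r + 1.48, 0, 0)
  o1 <- c7 + 1.23 * c(cos(55 * deg), sin(55 * deg), 0)
  o2 <- c7 + 1.36 * c(cos(-55 * deg), sin(-55 * deg), 0)
  ho2 <- o2 + 0.97 * c(cos(-5 * deg), sin(-5 * deg), 0)
  hyd <- function(th_deg) {          # ring hydroxyl at ring position angle
    o <- (ring_r + 1.36) * c(cos(th_deg * deg), sin(th_deg * deg), 0)
    h <- o + 0.97 * c(cos((th_deg + 65) * deg), sin((th_deg + 65) * deg), 0)
    rbind(o, h)
  }
  xyz <- rbind(ring, c7, o1, o2, ho2, hyd(120), hyd(180), hyd(240))
  nm <- c(paste0("C", 1:6), "C7", "O1", "O2", "HO2",
          "O3", "HO3", "O4", "HO4", "O5", "HO5")
  el <- substr(nm, 1, 1)
  el[el == "H"] <- "H"
  atoms <- data.frame(name = nm, element = el, resname = "GAL",
                      resid = resid, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], stringsAsFactors = FALSE)
  mol <- molecule("gallic_unit", atoms, net_charge = 0L,
                  protonation_label = "other")
  assign_charges_radii(mol, table)
}

#' Idealized helical poly(gallic acid) oligomer
#'
#' Stacks `n_units` gallic-acid units on a helical path (fixed rise and
#' twist about the z axis), emulating the stable helical conformation of
#' enzymatically polymerized gallic acid.  Every unit keeps the full
#' template charge set, so the oligomer is fully protonated with net
#' charge 0.  The rise/twist values are idealized constants, not a
#' quantum-chemically optimized geometry.
#'
#' @param n_units Number of gallic units (the study model uses 9).
#' @param rise Helical rise per unit, Å.
#' @param twist Helical twist per unit, degrees.
#' @param table Charge/radius template table.
#' @return A [molecule()] with `n_units` × 16 atoms and net charge 0.
#' @export
build_pgal_oligomer <- function(n_units = 9, rise = 3.6, twist = 36,
                                table = default_charge_table()) {
  if (n_units < 1) stop("n_units must be >= 1")
  unit <- build_gallic_unit(table = table)
  parts <- vector("list", n_units)
  for (k in seq_len(n_units)) {
    th <- (k - 1) * twist * pi / 180
    rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    xyz <- coords(unit) %*% t(rot)
    xyz[, 3] <- xyz[, 3] + (k - 1) * rise
    at <- unit$atoms
    at$resid <- k
    at[, c("x", "y", "z")] <- xyz
    parts[[k]] <- at
  }
  molecule(sprintf("pgal_%d", n_units), do.call(rbind, parts),
           net_charge = 0L, protonation_label = "fully_protonated_polymer")
}

#' Idealized L-histidine in one of two protonation states
#'
#' Both states share the same heavy-atom skeleton: ammonium nitrogen with
#' three explicit hydrogens, carboxylate, and the imidazole five-ring built
#' as a regular pentagon.  `"protonated"` carries protons on both ring
#' nitrogens (imidazolium, net charge +1, both ring nitrogens donors);
#' `"zwitterionic"` carries HD1 only (neutral ring, NE2 acceptor, net
#' charge 0).
#'
#' @param state `"protonated"` or `"zwitterionic"`.
#' @param table Charge/radius template table.
#' @return A [molecule()].
#' @export
build_histidine <- function(state = c("protonated", "zwitterionic"),
                            table = default_charge_table()) {
  state <- match.arg(state)
  resname <- if (state == "protonated") "HIP" else "HID"
  pos <- list(
    N   = c(0.00, 0.00, 0.00),
    H1  = c(-0.47, 0.82, 0.33),
    H2  = c(-0.47, -0.82, 0.33),
    H3  = c(-0.47, 0.00, -0.88),
    CA  = c(1.47, 0.00, 0.00),
    C   = c(2.11, 1.40, 0.00),
    O   = c(1.66, 2.36, 0.60),
    OXT = c(3.19, 1.62, -0.62),
    CB  = c(2.07, -0.77, -1.20),
    CG  = c(3.57, -0.90, -1.15))
  # imidazole: regular pentagon (side 1.37 Angstrom) in the z = const plane
  # of CG, centre displaced from CG; ring order CG-ND1-CE1-NE2-CD2
  side <- 1.37
  circ <- side / (2 * sin(pi / 5))
  u <- c(0.94, 0.34, 0) / sqrt(0.94^2 + 0.34^2)
  ctr <- pos$CG + circ * u
  a0 <- atan2(pos$CG[2] - ctr[2], pos$CG[1] - ctr[1])
  ring_names <- c("CG", "ND1", "CE1", "NE2", "CD2")
  for (k in 2:5) {
    a <- a0 + (k - 1) * 2 * pi / 5
    pos[[ring_names[k]]] <- c(ctr[1] + circ * cos(a),
                              ctr[2] + circ * sin(a), ctr[3])
  }
  radial <- function(p) {
    v <- p - ctr
    p + 1.00 * v / sqrt(sum(v^2))
  }
  pos$HD1 <- radial(pos$ND1)
  if (state == "protonated") pos$HE2 <- radial(pos$NE2)
  ord <- c("N", "H1", "H2", "H3", "CA", "C", "O", "OXT", "CB", "CG",
           "ND1", "HD1", "CD2", "CE1", "NE2",
           if (state == "protonated") "HE2")
  xyz <- do.call(rbind, pos[ord])
  el <- substr(ord, 1, 1)
  atoms <- data.frame(name = ord, element = el, resname = resname,
                      resid = 1, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  mol <- molecule(paste0("his_", state), atoms,
                  net_charge = if (state == "protonated") 1L else 0L,
                  protonation_label = state)
  assign_charges_radii(mol, table)
}

# ------------------------------------------------------------------
# Rigid-body pose sampling

#' Uniform random rotation as a unit quaternion
#'
#' Shoemake's subgroup algorithm: three uniforms map to a versor uniform on
#' SO(3).  Draws from the current RNG stream.
#'
#' @return Numeric length-4 unit quaternion `(w, x, y, z)`.
#' @export
random_versor <- function() {
  u <- runif(3)
  q <- c(sqrt(u[1]) * cos(2 * pi * u[3]),
         sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]))
  q / sqrt(sum(q^2))
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q Length-4 numeric `(w, x, y, z)` with unit norm.
#' @return 3 x 3 rotation matrix.
#' @export
versor_to_matrix <- function(q) {
  if (abs(sum(q^2) - 1) > 1e-9) stop("versor must have unit norm")
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Apply a rigid-body pose to the ligand
#'
#' The pose rotates the ligand about its centroid by the stored versor and
#' places the rotated centroid at the stored translation.
#'
#' @param pose One row of a pose table (list or data frame row with `qw`,
#'   `qx`, `qy`, `qz`, `tx`, `ty`, `tz`).
#' @param ligand A [molecule()].
#' @return The posed ligand as a [molecule()].
#' @export
apply_pose <- function(pose, ligand) {
  q <- as.numeric(c(pose$qw, pose$qx, pose$qy, pose$qz))
  tr <- as.numeric(c(pose$tx, pose$ty, pose$tz))
  xyz <- coords(ligand)
  ctr <- colMeans(xyz)
  rot <- versor_to_matrix(q)
  new_xyz <- sweep(xyz, 2, ctr) %*% t(rot)
  new_xyz <- sweep(new_xyz, 2, tr, "+")
  out <- ligand
  out$atoms[, c("x", "y", "z")] <- new_xyz
  out
}

#' Sample seeded rigid-body complex poses in a contact shell
#'
#' Emulates a docking campaign's pose ensemble: for each pose a uniform
#' random orientation of the ligand and a random approach direction are
#' drawn, and the ligand is slid along the approach ray until the minimum
#' intermolecular atom distance hits a randomly chosen contact distance
#' within `[clash_min, contact_max]`.  Replicate `r` uses seed `seed + r - 1`,
#' mirroring a triplicated design; regenerating with the same seed
#' reproduces the transforms bit for bit.
#'
#' @param receptor,ligand [molecule()] objects.
#' @param n_poses Poses per replicate (study design: at least 50).
#' @param replicates Number of replicate runs (study design: 3).
#' @param seed Integer seed.
#' @param clash_min Minimum allowed intermolecular atom distance, Å.
#' @param contact_max Maximum allowed closest approach, Å (contact shell).
#' @param max_attempts Attempts per pose before giving up.
#' @return Object of class `pose_set`: list with `receptor`, `ligand`,
#'   `poses` (data frame: `pose_id`, `replicate`, `qw..qz`, `tx..tz`,
#'   `min_dist`), `seed`, `replicates`.
#' @export
sample_poses <- function(receptor, ligand, n_poses = 50, replicates = 3,
                         seed = 1, clash_min = 2.2, contact_max = 4.5,
                         max_attempts = 10000) {
  stopifnot(n_poses >= 1, replicates >= 1, clash_min > 0,
            contact_max > clash_min)
  rec_xyz <- coords(receptor)
  rec_ctr <- colMeans(rec_xyz)
  lig_xyz0 <- coords(ligand)
  lig_ctr <- colMeans(lig_xyz0)
  lig_local <- sweep(lig_xyz0, 2, lig_ctr)
  rec_span <- max(sqrt(rowSums(sweep(rec_xyz, 2, rec_ctr)^2)))
  lig_span <- max(sqrt(rowSums(lig_local^2)))
  t_far <- rec_span + lig_span + contact_max + 5

  mind_at <- function(rot_lig, u, t) {
    pos <- sweep(rot_lig, 2, rec_ctr + u * t, "+")
    min_cross_dist_cpp(rec_xyz, pos)
  }

  rows <- vector("list", n_poses * replicates)
  n <- 0L
  for (r in seq_len(replicates)) {
    with_seed(seed + r - 1, {
      for (p in seq_len(n_poses)) {
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          q <- random_versor()
          rot_lig <- lig_local %*% t(versor_to_matrix(q))
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          target <- runif(1, clash_min + 0.1, contact_max - 0.1)
          # bracket: slide inward until below target
          t_hi <- t_far
          t_lo <- NA
          t <- t_far
          while (t > 0) {
            t <- t - 1
            d <- mind_at(rot_lig, u, t)
            if (d < target) { t_lo <- t; t_hi <- t + 1; break }
          }
          if (is.na(t_lo)) next
          for (b in 1:40) {
            tm <- (t_lo + t_hi) / 2
            if (mind_at(rot_lig, u, tm) < target) t_lo <- tm else t_hi <- tm
          }
          tfin <- t_hi
          dfin <- mind_at(rot_lig, u, tfin)
          if (dfin >= clash_min && dfin <= contact_max) {
            n <- n + 1L
            rows[[n]] <- data.frame(
              pose_id = p, replicate = r, qw = q[1], qx = q[2], qy = q[3],
              qz = q[4], tx = rec_ctr[1] + u[1] * tfin,
              ty = rec_ctr[2] + u[2] * tfin, tz = rec_ctr[3] + u[3] * tfin,
              min_dist = dfin)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop(sprintf(
            "pose sampling exhausted after %d attempts (replicate %d, pose %d)",
            max_attempts, r, p))
      }
    })
  }
  structure(list(receptor = receptor, ligand = ligand,
                 poses = do.call(rbind, rows), seed = seed,
                 replicates = replicates, clash_min = clash_min,
                 contact_max = contact_max),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set> %d poses (%d x %d replicates), seed %d\n",
              nrow(x$poses), nrow(x$poses) / x$replicates, x$replicates,
              x$seed))
  invisible(x)
}

#' Write a pose ensemble to disk
#'
#' Writes a plain-text transform table (`pose_id`, `replicate`, versor,
#' translation, closest approach) and, optionally, a multi-model PDB of the
#' posed complexes.
#'
#' @param poseset A `pose_set` from [sample_poses()].
#' @param table_path Path for the transform table (TSV).
#' @param pdb_path Optional path for a multi-model PDB.
#' @return `table_path`, invisibly.
#' @export
write_pose_set <- function(poseset, table_path, pdb_path = NULL) {
  utils::write.table(format(poseset$poses, digits = 12), table_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pdb_path)) {
    con <- file(pdb_path, "w")
    on.exit(close(con))
    tmp <- tempfile(fileext = ".pdb")
    for (i in seq_len(nrow(poseset$poses))) {
      posed <- apply_pose(poseset$poses[i, ], poseset$ligand)
      cmplx <- combine_molecules(poseset$receptor, posed)
      write_pdb(cmplx, tmp)
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(grep("^(ATOM|HETATM|TER)", readLines(tmp), value = TRUE),
                 con)
      writeLines("ENDMDL", con)
    }
    unlink(tmp)
  }
  invisible(table_path)
}
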