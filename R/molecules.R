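#' Construct a molecule
#'
#' A molecule is an ordered table of point atoms carrying Cartesian
#' coordinates (Å), optional partial charges (elementary charges), optional
#' hard-sphere radii (Å) and a hydrogen-bond role, together with a declared
#' integer net charge and a protonation label.  This is the unit every
#' energy and surface function operates on.
#'
#' @param id Character identifier.
#' @param atoms Data frame with columns `name`, `element`, `resname`,
#'   `resid`, `x`, `y`, `z` and optionally `charge`, `radius`, `hbond_role`
#'   (one of `"donor"`, `"acceptor"`, `"both"`, `"none"`).
#' @param net_charge Declared integer net charge (elementary charges).
#' @param protonation_label One of `"protonated"`, `"zwitterionic"`,
#'   `"fully_protonated_polymer"`, `"other"`.
#' @param validate Check structural invariants (finite coordinates, minimum
#'   interatomic separation 0.7 Å, charges within \[−2, +2\]).
#' @return Object of class `molecule`.
#' @export
molecule <- function(id, atoms, net_charge = NA_integer_,
                     protonation_label = "other", validate = TRUE) {
  stopifnot(is.data.frame(atoms))
  needed <- c("name", "element", "resname", "resid", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  if (is.null(atoms$hbond_role)) atoms$hbond_role <- "none"
  rownames(atoms) <- NULL
  mol <- structure(list(id = as.character(id), atoms = atoms,
                        net_charge = net_charge,
                        protonation_label = protonation_label),
                   class = "molecule")
  if (validate) validate_molecule(mol)
  mol
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms, net charge %s, %s\n", x$id,
              nrow(x$atoms),
              ifelse(is.na(x$net_charge), "?", format(x$net_charge)),
              x$protonation_label))
  invisible(x)
}

#' @export
#' @rdname molecule
is.molecule <- function(x) inherits(x, "molecule")

#' Atom coordinates as a matrix
#'
#' @param mol A [molecule()].
#' @return Numeric n x 3 matrix of coordinates in Å.
#' @export
coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' Validate molecular invariants
#'
#' Checks finite coordinates, at least one atom, a minimum interatomic
#' separation of 0.7 Å (covalent sanity), partial charges within
#' \[−2, +2\], and — when all charges are assigned and a net charge is
#' declared — that the partial charges sum to the net charge within 1e−6.
#'
#' @param mol A [molecule()].
#' @param min_sep Minimum allowed interatomic distance in Å.
#' @return The molecule, invisibly; stops on violation.
#' @export
validate_molecule <- function(mol, min_sep = 0.7) {
  at <- mol$atoms
  if (nrow(at) < 1) stop("molecule '", mol$id, "' has no atoms")
  xyz <- coords(mol)
  if (!all(is.finite(xyz))) stop("non-finite coordinates in '", mol$id, "'")
  if (nrow(at) > 1) {
    d <- stats::dist(xyz)
    if (min(d) < min_sep)
      stop(sprintf("atoms closer than %.2f Angstrom in '%s' (min %.3f)",
                   min_sep, mol$id, min(d)))
  }
  q <- at$charge
  if (any(!is.na(q) & abs(q) > 2))
    stop("partial charge outside [-2, +2] in '", mol$id, "'")
  if (!anyNA(q) && !is.na(mol$net_charge)) {
    if (abs(sum(q) - mol$net_charge) > 1e-6)
      stop(sprintf("charges sum to %.8f, declared net charge %d in '%s'",
                   sum(q), mol$net_charge, mol$id))
  }
  invisible(mol)
}

# ------------------------------------------------------------------
# Charge / radius templates

#' Bundled charge, radius and hydrogen-bond role templates
#'
#' Per-atom template table keyed by (residue name, atom name) used to turn a
#' bare PDB structure into a PQR-ready one.  Values are Gasteiger-like
#' partial charges normalized so each residue sums exactly to its formal
#' charge: `GAL` (gallic-acid unit, 0), `HIP` (histidine with protonated
#' imidazolium, +1), `HID` (zwitterionic histidine with neutral imidazole,
#' 0).  Only polar hydrogens are present; nonpolar hydrogens are folded into
#' the heavy-atom radii.  The table is a plain data frame so alternative
#' charge models can be swapped in via [read_charge_table()].
#'
#' @return Data frame with columns `resname`, `atom`, `charge`, `radius`,
#'   `hbond_role`, `formal_charge`.
#' @export
default_charge_table <- function() {
  path <- system.file("extdata", "charge_radius_templates.tsv",
                      package = "polybind")
  read_charge_table(path)
}

#' Read / write a charge-radius template table
#'
#' Tab-separated text with columns `resname`, `atom`, `charge`, `radius`,
#' `hbond_role`, `formal_charge` (the residue's formal integer charge,
#' repeated on each of its rows).  On read, each residue's template charges
#' are checked to sum to its formal charge within 1e−6.
#'
#' @param path File path.
#' @return Data frame (for `read_charge_table`).
#' @export
read_charge_table <- function(path) {
  if (!file.exists(path)) stop("charge table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  needed <- c("resname", "atom", "charge", "radius", "hbond_role",
              "formal_charge")
  if (!all(needed %in% names(tab)))
    stop("charge table must have columns: ", paste(needed, collapse = ", "))
  for (rn in unique(tab$resname)) {
    sub <- tab[tab$resname == rn, ]
    if (abs(sum(sub$charge) - sub$formal_charge[1]) > 1e-6)
      stop(sprintf("template '%s' charges sum to %.6f, formal charge %d",
                   rn, sum(sub$charge), sub$formal_charge[1]))
  }
  tab
}

#' @param table Data frame as returned by [default_charge_table()].
#' @rdname read_charge_table
#' @export
write_charge_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assign partial charges, radii and H-bond roles from a template table
#'
#' Looks up every atom by its (residue name, atom name) pair and copies the
#' template charge, radius and hydrogen-bond role.  Idempotent.  After
#' assignment the molecule's partial charges must sum to its declared net
#' charge (checked when `net_charge` is set).
#'
#' @param mol A [molecule()].
#' @param table Template table; defaults to [default_charge_table()].
#' @return The molecule with `charge`, `radius`, `hbond_role` filled in.
#' @export
assign_charges_radii <- function(mol, table = default_charge_table()) {
  at <- mol$atoms
  if (nrow(at) == 0) return(mol)
  key <- paste(at$resname, at$name)
  tkey <- paste(table$resname, table$atom)
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("no template entry for atom(s): ", paste(bad, collapse = ", "))
  }
  at$charge <- table$charge[idx]
  at$radius <- table$radius[idx]
  at$hbond_role <- table$hbond_role[idx]
  mol$atoms <- at
  validate_molecule(mol)
  mol
}

# ------------------------------------------------------------------
# PDB / PQR input and output (via bio3d)

.bio3d_to_atoms <- function(pdb, with_charge = FALSE) {
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(a$elety), 1, 1)
  atoms <- data.frame(name = trimws(a$elety), element = trimws(elem),
                      resname = trimws(a$resid), resid = a$resno,
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  if (with_charge) {
    atoms$charge <- a$o
    atoms$radius <- a$b
  }
  atoms$hbond_role <- "none"
  atoms
}

.atoms_to_bio3d <- function(mol) {
  at <- mol$atoms
  xyz <- as.numeric(t(coords(mol)))
  pdb <- list(atom = data.frame(
    type = "ATOM", eleno = seq_len(nrow(at)), elety = at$name, alt = NA,
    resid = at$resname, chain = "A", resno = at$resid, insert = NA,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$charge), 0, at$charge),
    b = ifelse(is.na(at$radius), 0, at$radius),
    segid = NA, elesy = at$element, charge = NA,
    stringsAsFactors = FALSE), xyz = xyz)
  class(pdb) <- "pdb"
  pdb
}

#' Read a molecule from a PDB file
#'
#' Parses ATOM/HETATM records (through \pkg{bio3d}).  Charges and radii are
#' left unassigned; use [assign_charges_radii()] before any energy or
#' surface computation.
#'
#' @param path Path to a PDB file with at least one ATOM/HETATM record.
#' @param id Identifier for the molecule; defaults to the file name.
#' @param net_charge,protonation_label Passed to [molecule()].
#' @return A [molecule()].
#' @export
read_pdb <- function(path, id = basename(path), net_charge = NA_integer_,
                     protonation_label = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("no ATOM/HETATM records in '", path, "'")
  molecule(id, .bio3d_to_atoms(pdb), net_charge = net_charge,
           protonation_label = protonation_label)
}

#' Read a molecule from a PQR file
#'
#' PQR is the whitespace-delimited PDB dialect whose last two numeric
#' fields per atom are the partial charge (e) and radius (Å).
#'
#' @inheritParams read_pdb
#' @return A [molecule()] with charges and radii populated.
#' @export
read_pqr <- function(path, id = basename(path), net_charge = NA_integer_,
                     protonation_label = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  pqr <- tryCatch(bio3d::read.pqr(path, verbose = FALSE),
                  error = function(e) stop("PQR parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(pqr$atom) || nrow(pqr$atom) == 0)
    stop("no ATOM records in '", path, "'")
  molecule(id, .bio3d_to_atoms(pqr, with_charge = TRUE),
           net_charge = net_charge, protonation_label = protonation_label)
}

#' Write a molecule to PDB or PQR
#'
#' `write_pqr()` refuses to write atoms lacking an assigned charge or a
#' positive radius; both fields are emitted with four decimals so a
#' read-back reproduces them to 1e−4.
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(mol, path) {
  at <- mol$atoms
  if (anyNA(at$charge))
    stop("cannot write PQR: unassigned charge in '", mol$id, "'")
  if (anyNA(at$radius) || any(at$radius <= 0))
    stop("cannot write PQR: missing or non-positive radius in '",
         mol$id, "'")
  pdb <- .atoms_to_bio3d(mol)
  bio3d::write.pqr(pdb = pdb, o = pdb$atom$o, b = pdb$atom$b, file = path)
  invisible(path)
}

#' @rdname write_pqr
#' @export
write_pdb <- function(mol, path) {
  pdb <- .atoms_to_bio3d(mol)
  bio3d::write.pdb(pdb = pdb, file = path)
  invisible(path)
}

# Merge two molecules into one rigid complex (atom tables stacked; receptor
# atoms first).  Net charge adds when both declared.
combine_molecules <- function(receptor, ligand, id = "complex") {
  nc <- if (!is.na(receptor$net_charge) && !is.na(ligand$net_charge))
    receptor$net_charge + ligand$net_charge else NA_integer_
  molecule(id, rbind(receptor$atoms, ligand$atoms), net_charge = nc,
           protonation_label = "other")
}
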