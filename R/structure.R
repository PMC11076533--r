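# Structure representation and geometry shared by all modules.
#
# Coordinates are stored in nm (PDB Angstroms are converted on read) so the
# restraint cutoffs (1.2/1.8 nm), the contact cutoff (0.6 nm) and the H-bond
# cutoff (0.35 nm) can be used without unit juggling. Atom indices are
# 1-based row indices into the atom table; emitted index files are 1-based
# as the .ndx format requires.

.water_resnames <- c("HOH", "WAT", "SOL", "TIP3", "TIP4", "TIP5", "SPC",
                     "SPCE", "H2O", "DOD")
.ion_resnames <- c("NA", "CL", "K", "MG", "ZN", "CA", "MN", "FE", "CU",
                   "NI", "CD", "CO", "SR", "CS", "BR", "LI", "RB", "F",
                   "IOD", "YB", "PT", "AU", "HG")

#' Construct a structure object from an atom table
#'
#' Low-level constructor; most users will call [read_pdb()]. The atom table
#' must have one row per atom with columns `name`, `element`, `resid`
#' (residue number), `resname`, `chain`, `x`, `y`, `z` (nm) and the logical
#' `is_ligand`. Every atom belongs to exactly one of the protein
#' (`is_ligand = FALSE`) or the ligand; waters and ions are excluded before
#' construction.
#'
#' @param atoms data.frame as described above.
#' @param ligand_selector the rule (residue names, optionally a chain) that
#'   identified the ligand; stored for provenance.
#' @return An object of class `pdb_structure`.
#' @export
pdb_structure <- function(atoms, ligand_selector = NULL) {
  req <- c("name", "element", "resid", "resname", "chain", "x", "y", "z",
           "is_ligand")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$element)))
    stop("empty element symbols")
  if (!any(!atoms$is_ligand & atoms$name == "CA" & toupper(atoms$element) == "C"))
    stop("structure has no protein C-alpha atom")
  if (!any(atoms$is_ligand & toupper(atoms$element) != "H"))
    stop("structure has no ligand heavy atom")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, ligand_selector = ligand_selector),
            class = "pdb_structure")
}

#' Read a protein-ligand complex from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), converts coordinates to nm,
#' resolves alternate locations to the highest-occupancy copy (ties: first
#' encountered), removes crystallographic waters and common monoatomic
#' ions, and flags the ligand by residue name (and optionally chain).
#' Ligand identification is explicit: no automatic het-group guessing.
#'
#' @param path PDB file.
#' @param ligand character vector of residue names identifying the ligand.
#' @param ligand_chain optional chain id restricting the ligand match.
#' @param keep_waters keep waters/ions instead of dropping them (rare).
#' @return A [pdb_structure] object.
#' @examples
#' pdb <- write_demo_pdb(tempfile(fileext = ".pdb"))
#' s <- read_pdb(pdb, ligand = "LIG")
#' s
#' @export
read_pdb <- function(path, ligand, ligand_chain = NULL, keep_waters = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom

  # alternate locations: keep highest occupancy per (chain, resno, insert, name)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(nzchar(alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    occ <- at$o
    occ[is.na(occ)] <- 1
    ord <- order(key, -occ, seq_len(nrow(at)))
    keep <- !duplicated(key[ord])
    rows <- sort(ord[keep])
    at <- at[rows, , drop = FALSE]
  }

  element <- at$elesy
  element[is.na(element)] <- ""
  element <- toupper(trimws(element))
  guess <- toupper(sub("^[0-9']*", "", at$elety))
  guess <- substr(guess, 1, 1)
  element[!nzchar(element)] <- guess[!nzchar(element)]

  chain <- at$chain
  chain[is.na(chain)] <- ""
  resname <- toupper(trimws(at$resid))

  is_ligand <- resname %in% toupper(ligand)
  if (!is.null(ligand_chain)) is_ligand <- is_ligand & chain %in% ligand_chain
  if (!any(is_ligand))
    stop("ligand selector matched no residue: ",
         paste(ligand, collapse = ","),
         if (!is.null(ligand_chain)) paste0(" (chain ", ligand_chain, ")"))

  atoms <- data.frame(
    name = trimws(at$elety), element = element, resid = at$resno,
    resname = resname, chain = chain,
    x = at$x / 10, y = at$y / 10, z = at$z / 10,
    occ = ifelse(is.na(at$o), 1, at$o), is_ligand = is_ligand,
    stringsAsFactors = FALSE)

  if (!keep_waters) {
    water <- atoms$resname %in% .water_resnames & !atoms$is_ligand
    natoms_res <- ave(seq_len(nrow(atoms)),
                      paste(atoms$chain, atoms$resid, atoms$resname),
                      FUN = length)
    ion <- atoms$resname %in% .ion_resnames & natoms_res == 1 & !atoms$is_ligand
    atoms <- atoms[!(water | ion), , drop = FALSE]
  }

  pdb_structure(atoms,
                ligand_selector = list(resname = ligand, chain = ligand_chain))
}

#' Write a structure to a PDB file
#'
#' Coordinates are written in Angstroms at the format's 3-decimal precision,
#' ligand atoms as HETATM records.
#'
#' @param structure a [pdb_structure].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]) * 10)),
    type = ifelse(a$is_ligand, "HETATM", "ATOM"),
    resno = a$resid, resid = a$resname, eleno = seq_len(nrow(a)),
    elety = a$name, chain = ifelse(nzchar(a$chain), a$chain, " "),
    o = a$occ, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms
  p <- a[!a$is_ligand, ]
  l <- a[a$is_ligand, ]
  cat("pdb_structure:", nrow(a), "atoms\n")
  cat("  protein:", nrow(p), "atoms,",
      length(unique(paste(p$chain, p$resid))), "residues,",
      length(calpha_atoms(x)), "C-alpha\n")
  cat("  ligand :", nrow(l), "atoms (",
      paste(unique(l$resname), collapse = ","), ")\n")
  invisible(x)
}

#' Number of protein residues in a structure
#' @param structure a [pdb_structure].
#' @return integer count of distinct (chain, residue number) pairs.
#' @export
n_protein_residues <- function(structure) {
  p <- structure$atoms[!structure$atoms$is_ligand, ]
  length(unique(paste(p$chain, p$resid)))
}

#' Atom coordinate matrix
#' @param structure a [pdb_structure].
#' @return numeric matrix, one row per atom, columns x/y/z in nm.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Protein heavy atoms (C, N, O, S)
#'
#' The restraint scheme that fixes "all heavy atoms" selects exactly the
#' protein atoms whose element is carbon, nitrogen, oxygen or sulfur;
#' hydrogens and all ligand atoms are excluded.
#'
#' @param structure a [pdb_structure].
#' @return integer vector of atom indices.
#' @export
heavy_atoms <- function(structure) {
  a <- structure$atoms
  which(!a$is_ligand & toupper(a$element) %in% c("C", "N", "O", "S"))
}

#' Protein C-alpha atoms
#'
#' Backbone alpha-carbons: atoms named "CA" with element carbon on protein
#' residues. A calcium ion (also named "CA") is never selected because it is
#' not a protein atom and its element is not C.
#'
#' @param structure a [pdb_structure].
#' @return integer vector of atom indices.
#' @export
calpha_atoms <- function(structure) {
  a <- structure$atoms
  which(!a$is_ligand & a$name == "CA" & toupper(a$element) == "C")
}

#' Ligand atoms
#' @param structure a [pdb_structure].
#' @param heavy_only drop ligand hydrogens.
#' @return integer vector of atom indices.
#' @export
ligand_atoms <- function(structure, heavy_only = FALSE) {
  a <- structure$atoms
  i <- which(a$is_ligand)
  if (heavy_only) i <- i[toupper(a$element[i]) != "H"]
  i
}

# squared pairwise distances between two coordinate matrices
.pair_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Minimum distance between two atom sets
#'
#' Minimum over all pairs of Euclidean distances, in nm. This is the
#' "smallest distance to one atom of the ligand" primitive the contact and
#' restraint machinery is built on.
#'
#' @param structure a [pdb_structure].
#' @param a,b non-empty integer index vectors.
#' @param frame optional coordinate matrix replacing the structure's own
#'   coordinates (e.g. a trajectory frame).
#' @return distance in nm.
#' @export
min_distance <- function(structure, a, b, frame = NULL) {
  if (!length(a) || !length(b)) stop("empty atom set")
  xyz <- if (is.null(frame)) coords(structure) else frame
  A <- xyz[a, , drop = FALSE]
  B <- xyz[b, , drop = FALSE]
  d2 <- .pair_dist2(A, B)
  # the crossprod expansion can lose precision near zero; recompute the
  # winning pair with the direct formula
  ij <- arrayInd(which.min(d2), dim(d2))
  sqrt(sum((A[ij[1], ] - B[ij[2], ])^2))
}

#' Center of mass (or geometry) of an atom set
#'
#' @param structure a [pdb_structure].
#' @param idx atom indices; default all ligand atoms.
#' @param weighting `"mass"` (standard atomic weights by element) or
#'   `"geometric"` (unweighted mean).
#' @param frame optional replacement coordinates.
#' @return length-3 numeric vector, nm.
#' @export
center_of_mass <- function(structure, idx = ligand_atoms(structure),
                           weighting = c("mass", "geometric"),
                           frame = NULL) {
  weighting <- match.arg(weighting)
  if (!length(idx)) stop("empty atom set")
  xyz <- if (is.null(frame)) coords(structure) else frame
  xyz <- xyz[idx, , drop = FALSE]
  w <- if (weighting == "mass")
    atomic_mass(structure$atoms$element[idx]) else rep(1, length(idx))
  as.numeric(colSums(xyz * w) / sum(w))
}

#' Write a tiny three-residue demo complex
#'
#' A synthetic three-glycine peptide plus a two-atom "LIG" ligand, used in
#' examples and tests. Entirely constructed; resembles no deposited entry.
#'
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_demo_pdb <- function(path) {
  lines <- c(
    "REMARK  synthetic demo complex (three glycines + LIG)",
    .pdb_atom_line(1, "N",  "GLY", "A", 1, c(0.0, 0.0, 0.0), "N"),
    .pdb_atom_line(2, "CA", "GLY", "A", 1, c(1.5, 0.0, 0.0), "C"),
    .pdb_atom_line(3, "C",  "GLY", "A", 1, c(2.2, 1.3, 0.0), "C"),
    .pdb_atom_line(4, "O",  "GLY", "A", 1, c(1.7, 2.4, 0.0), "O"),
    .pdb_atom_line(5, "N",  "GLY", "A", 2, c(3.5, 1.2, 0.0), "N"),
    .pdb_atom_line(6, "CA", "GLY", "A", 2, c(4.4, 2.4, 0.0), "C"),
    .pdb_atom_line(7, "C",  "GLY", "A", 2, c(5.8, 2.0, 0.3), "C"),
    .pdb_atom_line(8, "O",  "GLY", "A", 2, c(6.2, 0.9, 0.1), "O"),
    .pdb_atom_line(9, "N",  "GLY", "A", 3, c(6.6, 3.0, 0.7), "N"),
    .pdb_atom_line(10, "CA", "GLY", "A", 3, c(8.0, 2.8, 1.0), "C"),
    .pdb_atom_line(11, "C",  "GLY", "A", 3, c(8.8, 4.1, 1.1), "C"),
    .pdb_atom_line(12, "O",  "GLY", "A", 3, c(8.3, 5.2, 1.0), "O"),
    .pdb_hetatm_line(13, "C1", "LIG", "A", 10, c(4.0, 5.0, 3.0), "C"),
    .pdb_hetatm_line(14, "O1", "LIG", "A", 10, c(5.2, 5.5, 3.2), "O"),
    "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write trajectory frames as a multi-model PDB
#'
#' @param structure a [pdb_structure] giving the atom records.
#' @param frames list of N x 3 coordinate matrices, nm.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frames <- function(structure, frames, path) {
  a <- structure$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    fr <- frames[[m]] * 10  # nm -> Angstrom
    if (nrow(fr) != nrow(a)) stop("frame ", m, " atom count mismatch")
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(vapply(seq_len(nrow(a)), function(i) {
      .pdb_record(if (a$is_ligand[i]) "HETATM" else "ATOM", i, a$name[i],
                  a$resname[i], if (nzchar(a$chain[i])) a$chain[i] else "A",
                  a$resid[i], fr[i, ], a$element[i])
    }, ""), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read trajectory frames from a multi-model PDB
#'
#' @param path multi-model PDB file.
#' @return list of N x 3 coordinate matrices, nm.
#' @export
read_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)),
         function(m) matrix(xyz[m, ], ncol = 3, byrow = TRUE) / 10)
}

.pdb_record <- function(rec, serial, name, resn, chain, resi, xyz, elem) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name, "", resn, chain, resi, "",
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, elem)
}
.pdb_atom_line <- function(serial, name, resn, chain, resi, xyz, elem)
  .pdb_record("ATOM", serial, name, resn, chain, resi, xyz, elem)
.pdb_hetatm_line <- function(serial, name, resn, chain, resi, xyz, elem)
  .pdb_record("HETATM", serial, name, resn, chain, resi, xyz, elem)
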