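# Six position-restraint selection schemes for SMD pulling, plus the
# rigid rotation that aligns a user-supplied pulling direction with +Z and
# writers for GROMACS-style index (.ndx) and position-restraint (.itp)
# files.
#
# The modes, in order of decreasing rigidity of the receptor:
#   1  all protein heavy atoms (C, N, O, S)
#   2  all C-alpha atoms
#   3  C-alpha with minimum 3-D distance to the ligand  > d_axial (1.2 nm)
#   4  C-alpha with along-axis (Z) distance to ligand   > d_axial (1.2 nm)
#   5  mode 4 AND in-plane radial distance to ligand    < d_radial (1.2 nm)
#   6  mode 5 with the along-axis cutoff raised to 1.8 nm
# Modes 3-6 presuppose the structure has been rotated so the pulling
# direction is +Z (align_pull_axis_to_z). Cutoff inequalities are strict.

#' Define a pulling axis
#'
#' @param direction length-3 vector; normalised internally. Zero errors.
#' @param origin reference point on the ligand, nm (default origin).
#' @return An object of class `pull_axis` with a unit `direction`.
#' @export
pull_axis <- function(direction, origin = c(0, 0, 0)) {
  direction <- as.numeric(direction)
  n <- sqrt(sum(direction^2))
  if (!is.finite(n) || n == 0) stop("pulling direction must be non-zero")
  structure(list(direction = direction / n, origin = as.numeric(origin)),
            class = "pull_axis")
}

# Rodrigues rotation taking unit vector d onto +Z.
.rotation_to_z <- function(d) {
  z <- c(0, 0, 1)
  cosang <- sum(d * z)
  if (cosang > 1 - 1e-14) return(diag(3))
  if (cosang < -1 + 1e-14) return(diag(c(1, -1, -1)))  # pi about x
  u <- c(d[2] * z[3] - d[3] * z[2],
         d[3] * z[1] - d[1] * z[3],
         d[1] * z[2] - d[2] * z[1])
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  sinang <- sqrt(max(0, 1 - cosang^2))
  diag(3) + sinang * K + (1 - cosang) * (K %*% K)
}

#' Rigidly rotate a structure so the pulling direction becomes +Z
#'
#' Distances are preserved; the rotation is applied about the axis origin.
#'
#' @param structure a [pdb_structure].
#' @param axis a [pull_axis].
#' @return list with elements `structure` (rotated copy) and `frame`
#'   (class `rotation_frame`: 3x3 matrix and the origin it was applied at).
#' @export
align_pull_axis_to_z <- function(structure, axis) {
  if (!inherits(axis, "pull_axis")) axis <- pull_axis(axis)
  R <- .rotation_to_z(axis$direction)
  xyz <- coords(structure)
  xyz <- sweep(xyz, 2, axis$origin)
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, axis$origin, "+")
  out <- structure
  out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]; out$atoms$z <- xyz[, 3]
  frame <- structure(list(matrix = R, applied_origin = axis$origin),
                     class = "rotation_frame")
  list(structure = out, frame = frame)
}

# Per-Calpha distances to the ligand in the aligned frame.
# reference "min": minimum over ligand heavy atoms (component-wise for the
# axial/radial variants); "com": distance to the ligand mass-weighted COM.
.mode_distances <- function(structure, reference) {
  ca <- calpha_atoms(structure)
  lig <- ligand_atoms(structure, heavy_only = TRUE)
  if (!length(lig)) stop("ligand has no heavy atoms")
  xyz <- coords(structure)
  A <- xyz[ca, , drop = FALSE]
  if (reference == "com") {
    L <- matrix(center_of_mass(structure, ligand_atoms(structure)), 1, 3)
  } else {
    L <- xyz[lig, , drop = FALSE]
  }
  dz <- abs(outer(A[, 3], L[, 3], "-"))
  dr2 <- outer(A[, 1], L[, 1], "-")^2 + outer(A[, 2], L[, 2], "-")^2
  d3 <- sqrt(dr2 + dz^2)
  list(ca = ca,
       d3 = apply(d3, 1, min),
       dz = apply(dz, 1, min),
       dr = sqrt(apply(dr2, 1, min)))
}

#' Select the restrained atom set for a given mode
#'
#' For modes 3-6 the structure must already be aligned so the pulling axis
#' is +Z. "Distance to ligand" is the minimum over ligand heavy atoms by
#' default; `reference = "com"` measures to the ligand's mass-weighted
#' center of mass instead. Inequalities are strict, so an atom exactly at a
#' cutoff is not selected by a ">" condition.
#'
#' @param structure a [pdb_structure], pulling axis along +Z.
#' @param mode integer 1-6.
#' @param d_axial along-axis (modes 4-6) or 3-D (mode 3) cutoff in nm;
#'   default 1.2 nm, except mode 6 where it defaults to 1.8 nm.
#' @param d_radial in-plane radial cutoff for modes 5-6, nm (default 1.2).
#' @param reference `"min"` or `"com"`, see above.
#' @return integer vector of selected atom indices.
#' @export
select_mode <- function(structure, mode, d_axial = NULL, d_radial = 1.2,
                        reference = c("min", "com")) {
  reference <- match.arg(reference)
  if (!mode %in% 1:6) stop("unknown restraint mode: ", mode)
  if (is.null(d_axial)) d_axial <- if (mode == 6) 1.8 else 1.2
  if (d_axial <= 0 || d_radial <= 0) stop("cutoffs must be positive")
  if (mode == 1) return(heavy_atoms(structure))
  if (mode == 2) return(calpha_atoms(structure))
  d <- .mode_distances(structure, reference)
  keep <- switch(as.character(mode),
    "3" = d$d3 > d_axial,
    "4" = d$dz > d_axial,
    "5" = d$dz > d_axial & d$dr < d_radial,
    "6" = d$dz > d_axial & d$dr < d_radial)
  d$ca[keep]
}

#' Build a full restraint specification
#'
#' Wraps [select_mode()] into an object carrying the mode, cutoffs,
#' reference rule, per-axis force constant and the selected atom set.
#'
#' @inheritParams select_mode
#' @param force_constant harmonic force constant per axis, kJ/mol/nm^2.
#' @return Object of class `restraint_spec`.
#' @export
build_restraints <- function(structure, mode, d_axial = NULL, d_radial = 1.2,
                             reference = c("min", "com"),
                             force_constant = 1000) {
  reference <- match.arg(reference)
  if (force_constant <= 0) stop("force_constant must be positive")
  if (is.null(d_axial)) d_axial <- if (mode == 6) 1.8 else 1.2
  sel <- select_mode(structure, mode, d_axial, d_radial, reference)
  structure(list(mode = mode, d_axial = d_axial, d_radial = d_radial,
                 reference = reference, force_constant = force_constant,
                 selected = sel, n_atoms = nrow(structure$atoms)),
            class = "restraint_spec")
}

#' @export
print.restraint_spec <- function(x, ...) {
  cat("restraint_spec: mode", x$mode, "-", length(x$selected),
      "restrained atoms of", x$n_atoms, "\n")
  cat("  cutoffs: axial", x$d_axial, "nm, radial", x$d_radial,
      "nm; reference:", x$reference, "\n")
  cat("  force constant:", x$force_constant, "kJ/mol/nm^2 per axis\n")
  invisible(x)
}

#' Write a GROMACS-style index group
#'
#' Emits a `[ name ]` section with 1-based atom indices, at most 15 per
#' line. An empty set errors: a restraint group must restrain something.
#'
#' @param indices integer atom indices (1-based).
#' @param name group name.
#' @param path output file.
#' @param append append to an existing .ndx file.
#' @return `path`, invisibly.
#' @export
write_index_group <- function(indices, name, path, append = FALSE) {
  indices <- as.integer(indices)
  if (!length(indices)) stop("refusing to write an empty index group")
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(sprintf("[ %s ]", name), con)
  for (i in seq(1, length(indices), by = 15)) {
    chunk <- indices[i:min(i + 14, length(indices))]
    writeLines(paste(sprintf("%6d", chunk), collapse = " "), con)
  }
  invisible(path)
}

#' Read index groups from a .ndx file
#'
#' @param path .ndx file.
#' @param name optional single group to return as an integer vector;
#'   otherwise a named list of all groups.
#' @return integer vector or named list of integer vectors.
#' @export
read_index_group <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  hdr <- grep("^\\[.*\\]$", lines)
  if (!length(hdr)) stop("no index groups in ", path)
  groups <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    g <- gsub("^\\[\\s*|\\s*\\]$", "", lines[hdr[k]])
    body <- lines[seq(hdr[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[nzchar(body)]
    groups[[g]] <- as.integer(unlist(strsplit(paste(body, collapse = " "),
                                              "\\s+")))
  }
  if (!is.null(name)) {
    if (is.null(groups[[name]])) stop("no group named ", name)
    return(groups[[name]])
  }
  groups
}

#' Write a position-restraint include file
#'
#' One record per restrained atom: atom index, function type 1, and the
#' force constant on x, y and z (kJ/mol/nm^2).
#'
#' @param indices integer atom indices (1-based).
#' @param force_constant per-axis force constant, kJ/mol/nm^2; scalar or
#'   one value per atom.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_position_restraints <- function(indices, force_constant, path) {
  indices <- as.integer(indices)
  if (!length(indices)) stop("refusing to write an empty restraint file")
  if (any(force_constant <= 0)) stop("force_constant must be positive")
  k <- rep_len(force_constant, length(indices))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("[ position_restraints ]",
               "; atom  functype  fx      fy      fz"), con)
  writeLines(sprintf("%6d %5d %9g %9g %9g", indices, 1L, k, k, k), con)
  invisible(path)
}

#' Read a position-restraint include file
#' @param path file written by [write_position_restraints()].
#' @return data.frame with columns `index`, `functype`, `fx`, `fy`, `fz`.
#' @export
read_position_restraints <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[;\\[]", lines) & nzchar(trimws(lines))]
  d <- read.table(text = lines, col.names = c("index", "functype",
                                              "fx", "fy", "fz"))
  d
}
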