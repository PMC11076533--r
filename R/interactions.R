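# Geometric protein-ligand interaction metrics over trajectory frames:
# contacts (minimum-distance cutoff 0.6 nm), hydrogen bonds
# (donor-acceptor < 0.35 nm and D-H...A angle at the hydrogen > 135 deg),
# displacement-binned profiles, pairwise non-bonded interaction energy
# (LJ 12-6 + Coulomb within 1.0 nm), and the potential length L0 at which
# the interaction energy has decayed to zero.

#' Protein-ligand contacts in one frame
#'
#' A contact is a (protein heavy atom, ligand atom) pair closer than the
#' cutoff. Heavy atoms are C/N/O/S as in [heavy_atoms()]; all ligand atoms
#' participate.
#'
#' @param structure a [pdb_structure].
#' @param frame optional N x 3 coordinate matrix (nm) replacing the
#'   structure's coordinates; must match the atom count.
#' @param cutoff contact cutoff, nm (default 0.6).
#' @return list: `count` (number of contact pairs), `residues` (sorted
#'   protein residue ids with >= 1 contact), `pairs` (two-column matrix of
#'   atom indices).
#' @export
contacts <- function(structure, frame = NULL, cutoff = 0.6) {
  if (cutoff <= 0) stop("cutoff must be positive")
  xyz <- if (is.null(frame)) coords(structure) else as.matrix(frame)
  if (nrow(xyz) != nrow(structure$atoms))
    stop("frame has ", nrow(xyz), " rows but structure has ",
         nrow(structure$atoms), " atoms")
  p <- heavy_atoms(structure)
  l <- ligand_atoms(structure)
  d2 <- .pair_dist2(xyz[p, , drop = FALSE], xyz[l, , drop = FALSE])
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  res <- sort(unique(structure$atoms$resid[p[hit[, 1]]]))
  list(count = nrow(hit), residues = res,
       pairs = cbind(protein = p[hit[, 1]], ligand = l[hit[, 2]]))
}

#' Contact-residue census over an ensemble of frames
#'
#' The union, over every frame of every trajectory, of the protein
#' residues making at least one contact with the ligand. The size of this
#' union is the per-mode "number of residues that ever touch the ligand
#' during its escape".
#'
#' @param frames a list of coordinate matrices, or a list of such lists
#'   (one inner list per trajectory).
#' @param structure a [pdb_structure].
#' @param cutoff contact cutoff, nm.
#' @return list: `residues` (sorted ids), `count`.
#' @export
contact_residue_census <- function(frames, structure, cutoff = 0.6) {
  if (is.list(frames) && length(frames) && is.list(frames[[1]]) &&
      !is.matrix(frames[[1]]))
    frames <- unlist(frames, recursive = FALSE)
  res <- integer(0)
  for (fr in frames)
    res <- union(res, contacts(structure, frame = fr, cutoff = cutoff)$residues)
  list(residues = sort(res), count = length(res))
}

#' Hydrogen bonds in one frame
#'
#' Counts donor-hydrogen...acceptor triples with donor-acceptor distance
#' below `cutoff` and the angle at the hydrogen (between the donor and the
#' acceptor) above `angle_min`. The donor-hydrogen covalent mapping must be
#' supplied: `hydrogens[i]` is covalently bonded to `donors[i]`. Both
#' pulling directions (protein donor to ligand acceptor and vice versa)
#' are counted when both appear in the supplied sets.
#'
#' @param structure a [pdb_structure].
#' @param donors,hydrogens equal-length atom index vectors (parallel).
#' @param acceptors atom index vector.
#' @param frame optional coordinate matrix, nm.
#' @param cutoff donor-acceptor cutoff, nm (default 0.35).
#' @param angle_min minimum D-H...A angle, degrees (default 135).
#' @param intermolecular only count pairs with donor and acceptor on
#'   different molecules (protein vs ligand).
#' @return list: `count`, `triples` (matrix donor/hydrogen/acceptor).
#' @export
hydrogen_bonds <- function(structure, donors, hydrogens, acceptors,
                           frame = NULL, cutoff = 0.35, angle_min = 135,
                           intermolecular = TRUE) {
  if (length(donors) != length(hydrogens))
    stop("donors and hydrogens must be parallel vectors")
  if (cutoff <= 0 || angle_min <= 0 || angle_min >= 180)
    stop("invalid hydrogen-bond criteria")
  xyz <- if (is.null(frame)) coords(structure) else as.matrix(frame)
  if (!length(donors) || !length(acceptors))
    return(list(count = 0L, triples = matrix(0L, 0, 3)))
  is_lig <- structure$atoms$is_ligand
  cos_min <- cos(angle_min * pi / 180)
  keep <- matrix(0L, 0, 3)
  for (i in seq_along(hydrogens)) {
    d <- donors[i]; h <- hydrogens[i]
    acc <- acceptors[acceptors != d & acceptors != h]
    if (intermolecular) acc <- acc[is_lig[acc] != is_lig[d]]
    if (!length(acc)) next
    da <- xyz[acc, , drop = FALSE] - matrix(xyz[d, ], length(acc), 3,
                                            byrow = TRUE)
    dist_da <- sqrt(rowSums(da^2))
    hd <- xyz[d, ] - xyz[h, ]
    ha <- xyz[acc, , drop = FALSE] - matrix(xyz[h, ], length(acc), 3,
                                            byrow = TRUE)
    cosang <- (ha %*% hd) /
      (sqrt(rowSums(ha^2)) * sqrt(sum(hd^2)))
    # angle at H between donor and acceptor > angle_min
    # cos is decreasing: angle > angle_min <=> cos(angle) < cos(angle_min)
    ok <- dist_da < cutoff & as.numeric(cosang) < cos_min
    if (any(ok))
      keep <- rbind(keep, cbind(d, h, acc[ok]))
  }
  colnames(keep) <- c("donor", "hydrogen", "acceptor")
  list(count = nrow(keep), triples = keep)
}

#' Infer polar hydrogens and donor/acceptor sets from geometry
#'
#' Convenience for structures without explicit topology: each hydrogen is
#' assigned to the nearest N or O within `bond_cutoff`; those N/O are
#' donors, and every N/O is an acceptor. Hydrogens whose nearest N/O is
#' beyond the cutoff are treated as apolar and skipped.
#'
#' @param structure a [pdb_structure].
#' @param frame optional coordinate matrix, nm.
#' @param bond_cutoff covalent N-H/O-H cutoff, nm (default 0.12).
#' @return list: `donors`, `hydrogens` (parallel), `acceptors`.
#' @export
find_polar_hydrogens <- function(structure, frame = NULL,
                                 bond_cutoff = 0.12) {
  a <- structure$atoms
  xyz <- if (is.null(frame)) coords(structure) else as.matrix(frame)
  hs <- which(toupper(a$element) == "H")
  no <- which(toupper(a$element) %in% c("N", "O"))
  donors <- integer(0); hydrogens <- integer(0)
  if (length(hs) && length(no)) {
    d2 <- .pair_dist2(xyz[hs, , drop = FALSE], xyz[no, , drop = FALSE])
    j <- apply(d2, 1, which.min)
    ok <- d2[cbind(seq_along(hs), j)] < bond_cutoff^2
    hydrogens <- hs[ok]
    donors <- no[j[ok]]
  }
  list(donors = donors, hydrogens = hydrogens, acceptors = no)
}

#' Bin a per-frame metric by ligand displacement
#'
#' Frames fall into half-open bins `[lo, hi)`; each bin reports the
#' arithmetic mean of the metric over its frames and the frame count.
#' Empty bins carry NA means (flagged, not zero-filled).
#'
#' @param metric numeric per-frame values.
#' @param displacement numeric per-frame ligand displacements, nm.
#' @param edges increasing bin edges, nm.
#' @return data.frame of class `displacement_profile`: `lo`, `hi`, `mid`,
#'   `n`, `mean`.
#' @export
bin_by_displacement <- function(metric, displacement, edges) {
  if (length(metric) != length(displacement))
    stop("metric and displacement lengths differ")
  if (any(diff(edges) <= 0)) stop("edges must be increasing")
  bin <- findInterval(displacement, edges, left.open = FALSE,
                      rightmost.closed = FALSE)
  nb <- length(edges) - 1L
  n <- tabulate(bin[bin >= 1 & bin <= nb], nbins = nb)
  means <- rep(NA_real_, nb)
  for (b in seq_len(nb)) if (n[b] > 0) means[b] <- mean(metric[bin == b])
  out <- data.frame(lo = edges[-length(edges)], hi = edges[-1],
                    mid = (edges[-length(edges)] + edges[-1]) / 2,
                    n = n, mean = means)
  class(out) <- c("displacement_profile", "data.frame")
  out
}

#' Protein-ligand non-bonded interaction energy of one frame
#'
#' Sum over protein-ligand atom pairs within the cutoff of a 12-6
#' Lennard-Jones term (Lorentz-Berthelot combination: arithmetic sigma,
#' geometric epsilon) and a Coulomb term
#' \eqn{f q_i q_j / (\epsilon_r r)} with
#' \eqn{f = 138.935458} kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}. Pairs at or
#' beyond the cutoff contribute nothing (strict inequality).
#'
#' @param structure a [pdb_structure].
#' @param params data.frame with one row per atom (in atom order) and
#'   columns `charge` (e), `sigma` (nm), `epsilon` (kJ/mol).
#' @param frame optional coordinate matrix, nm.
#' @param cutoff pair cutoff, nm (default 1.0).
#' @param eps_r relative permittivity (default 1).
#' @return list: `IE`, `V_LJ`, `V_Coul`, all kcal/mol.
#' @export
interaction_energy <- function(structure, params, frame = NULL,
                               cutoff = 1.0, eps_r = 1) {
  a <- structure$atoms
  if (nrow(params) != nrow(a))
    stop("params must have one row per atom (", nrow(a), ")")
  need <- c("charge", "sigma", "epsilon")
  if (!all(need %in% names(params)))
    stop("params needs columns: ", paste(need, collapse = ", "))
  bad <- which(!stats::complete.cases(params[, need]))
  if (length(bad))
    stop("missing non-bonded parameters for atom(s): ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ...")
  xyz <- if (is.null(frame)) coords(structure) else as.matrix(frame)
  p <- which(!a$is_ligand)
  l <- which(a$is_ligand)
  d2 <- .pair_dist2(xyz[p, , drop = FALSE], xyz[l, , drop = FALSE])
  hit <- which(d2 < cutoff^2 & d2 > 0, arr.ind = TRUE)
  if (!nrow(hit)) return(list(IE = 0, V_LJ = 0, V_Coul = 0))
  i <- p[hit[, 1]]; j <- l[hit[, 2]]
  r <- sqrt(d2[hit])
  sig <- (params$sigma[i] + params$sigma[j]) / 2
  eps <- sqrt(params$epsilon[i] * params$epsilon[j])
  sr6 <- (sig / r)^6
  v_lj <- sum(4 * eps * (sr6^2 - sr6))
  v_c <- sum(rk_constants$coulomb_kJ * params$charge[i] * params$charge[j] /
               (eps_r * r))
  list(IE = kJ_to_kcal(v_lj + v_c), V_LJ = kJ_to_kcal(v_lj),
       V_Coul = kJ_to_kcal(v_c))
}

#' Potential length L0 from a displacement-binned IE profile
#'
#' The smallest bin center at which the magnitude of the interaction
#' energy drops below `epsilon_zero` and stays below for every larger
#' displacement (empty bins are skipped). If the profile never decays
#' below the threshold, NA is returned with a warning.
#'
#' @param profile a [bin_by_displacement()] result whose `mean` column is
#'   the interaction energy (kcal/mol).
#' @param epsilon_zero decay threshold, kcal/mol (default 1).
#' @return L0 in nm, or NA if the energy never decays.
#' @export
potential_length <- function(profile, epsilon_zero = 1) {
  ok <- !is.na(profile$mean)
  mid <- profile$mid[ok]
  ie <- abs(profile$mean[ok])
  below <- ie < epsilon_zero
  if (!any(below) || !below[length(below)]) {
    warning("interaction energy never decays below the threshold")
    return(NA_real_)
  }
  # last index where IE is at/above threshold; L0 is the next bin center
  above <- which(!below)
  if (!length(above)) return(mid[1])
  mid[max(above) + 1L]
}
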