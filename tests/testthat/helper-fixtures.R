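# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive loops so they share no code with the implementation.

# A random protein-ligand structure: n_res residues of N/CA/C/O (plus an
# amide H and an occasional SG), and a small "LIG" residue near the middle.
random_structure <- function(n_res = 8, seed = 1, lig_heavy = 3) {
  set.seed(seed)
  rows <- list()
  base <- c(0, 0, 0)
  for (r in seq_len(n_res)) {
    base <- base + stats::runif(3, 0.2, 0.5)
    for (nm in c("N", "CA", "C", "O")) {
      el <- substr(nm, 1, 1)
      rows[[length(rows) + 1]] <- data.frame(
        name = nm, element = el, resid = r, resname = "ALA", chain = "A",
        x = base[1] + stats::rnorm(1, 0, 0.05),
        y = base[2] + stats::rnorm(1, 0, 0.05),
        z = base[3] + stats::rnorm(1, 0, 0.05),
        occ = 1, is_ligand = FALSE, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      name = "H", element = "H", resid = r, resname = "ALA", chain = "A",
      x = base[1] + 0.1, y = base[2], z = base[3],
      occ = 1, is_ligand = FALSE, stringsAsFactors = FALSE)
    if (r %% 4 == 0)
      rows[[length(rows) + 1]] <- data.frame(
        name = "SG", element = "S", resid = r, resname = "CYS", chain = "A",
        x = base[1], y = base[2] + 0.15, z = base[3],
        occ = 1, is_ligand = FALSE, stringsAsFactors = FALSE)
  }
  center <- colMeans(do.call(rbind, rows)[, c("x", "y", "z")])
  for (j in seq_len(lig_heavy)) {
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("C", j), element = sample(c("C", "O", "N"), 1),
      resid = n_res + 1L, resname = "LIG", chain = "A",
      x = center[1] + stats::rnorm(1, 0, 0.1),
      y = center[2] + stats::rnorm(1, 0, 0.1),
      z = center[3] + stats::rnorm(1, 0, 0.1),
      occ = 1, is_ligand = TRUE, stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1]] <- data.frame(
    name = "H1", element = "H", resid = n_res + 1L, resname = "LIG",
    chain = "A", x = center[1] + 0.15, y = center[2], z = center[3],
    occ = 1, is_ligand = TRUE, stringsAsFactors = FALSE)
  pdb_structure(do.call(rbind, rows), ligand_selector = list(resname = "LIG"))
}

# --- brute-force oracles -------------------------------------------------

oracle_min_distance <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt(sum((A[i, ] - B[j, ])^2))
    if (d < best) best <- d
  }
  best
}

oracle_heavy <- function(structure) {
  a <- structure$atoms
  out <- integer(0)
  for (i in seq_len(nrow(a)))
    if (!a$is_ligand[i] && a$element[i] %in% c("C", "N", "O", "S"))
      out <- c(out, i)
  out
}

oracle_select_mode <- function(structure, mode, d_axial = NULL,
                               d_radial = 1.2) {
  if (is.null(d_axial)) d_axial <- if (mode == 6) 1.8 else 1.2
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (mode == 1) return(oracle_heavy(structure))
  ca <- which(!a$is_ligand & a$name == "CA" & a$element == "C")
  if (mode == 2) return(ca)
  lig <- which(a$is_ligand & a$element != "H")
  out <- integer(0)
  for (i in ca) {
    d3 <- dz <- dr <- Inf
    for (j in lig) {
      dd <- xyz[i, ] - xyz[j, ]
      d3 <- min(d3, sqrt(sum(dd^2)))
      dz <- min(dz, abs(dd[3]))
      dr <- min(dr, sqrt(dd[1]^2 + dd[2]^2))
    }
    keep <- switch(mode - 2L, d3 > d_axial, dz > d_axial,
                   dz > d_axial && dr < d_radial,
                   dz > d_axial && dr < d_radial)
    if (keep) out <- c(out, i)
  }
  out
}

oracle_contacts <- function(structure, frame, cutoff = 0.6) {
  a <- structure$atoms
  p <- oracle_heavy(structure)
  l <- which(a$is_ligand)
  count <- 0L
  res <- integer(0)
  for (i in p) for (j in l) {
    if (sqrt(sum((frame[i, ] - frame[j, ])^2)) < cutoff) {
      count <- count + 1L
      res <- union(res, a$resid[i])
    }
  }
  list(count = count, residues = sort(res))
}

oracle_hbonds <- function(structure, frame, donors, hydrogens, acceptors,
                          cutoff = 0.35, angle_min = 135) {
  is_lig <- structure$atoms$is_ligand
  count <- 0L
  for (q in seq_along(hydrogens)) {
    d <- donors[q]; h <- hydrogens[q]
    for (acc in acceptors) {
      if (acc == d || acc == h) next
      if (is_lig[acc] == is_lig[d]) next
      dist_da <- sqrt(sum((frame[d, ] - frame[acc, ])^2))
      if (dist_da >= cutoff) next
      v1 <- frame[d, ] - frame[h, ]
      v2 <- frame[acc, ] - frame[h, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang > angle_min) count <- count + 1L
    }
  }
  count
}

oracle_rmsd <- function(x, ref) {
  acc <- 0
  for (i in seq_len(nrow(x))) acc <- acc + sum((x[i, ] - ref[i, ])^2)
  sqrt(acc / nrow(x))
}

# A fast toy configuration for unit tests: short pull, sparse recording.
fast_toy_config <- function(...) {
  toy_config(duration = 1200, record_every = 10, frame_every = 5000, ...)
}
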