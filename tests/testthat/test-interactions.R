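# Interaction analysis: contacts, hydrogen bonds, displacement binning,
# non-bonded energies, potential length.

test_that("contacts honour the cutoff and report contributing residues", {
  atoms <- data.frame(
    name = c("CA", "CA", "C1"), element = "C",
    resid = c(1L, 2L, 3L), resname = c("GLY", "GLY", "LIG"), chain = "A",
    x = c(0, 0, 0), y = c(0, 0, 0), z = c(0.5, 2.0, 0), occ = 1,
    is_ligand = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  s <- pdb_structure(atoms)
  ct <- contacts(s)
  expect_equal(ct$count, 1)
  expect_equal(ct$residues, 1L)
  # everything out of range
  s2 <- s; s2$atoms$z <- c(5, 9, 0)
  ct2 <- contacts(s2)
  expect_equal(ct2$count, 0)
  expect_length(ct2$residues, 0)
  expect_error(contacts(s, frame = matrix(0, 2, 3)), "atoms")
})

test_that("contacts match the exhaustive pair scan on random frames", {
  for (seed in 1:15) {
    s <- random_structure(n_res = 6, seed = 300 + seed)
    frame <- coords(s) + matrix(stats::rnorm(3 * nrow(s$atoms), sd = 0.1),
                                ncol = 3)
    got <- contacts(s, frame = frame)
    want <- oracle_contacts(s, frame)
    expect_equal(got$count, want$count)
    expect_equal(got$residues, want$residues)
    # shrinking the cutoff never adds contacts
    expect_lte(contacts(s, frame = frame, cutoff = 0.4)$count, got$count)
  }
})

test_that("census is the union over frames and grows monotonically", {
  s <- random_structure(n_res = 8, seed = 77)
  set.seed(78)
  frames <- lapply(1:6, function(i)
    coords(s) + matrix(stats::rnorm(3 * nrow(s$atoms), sd = 0.15), ncol = 3))
  single <- contact_residue_census(frames[1], s)
  expect_equal(single$residues, contacts(s, frame = frames[[1]])$residues)
  prev <- 0L
  for (k in seq_along(frames)) {
    cen <- contact_residue_census(frames[seq_len(k)], s)
    expect_gte(cen$count, prev)
    prev <- cen$count
  }
  # nested list (trajectories of frames) flattens to the same union
  nested <- contact_residue_census(list(frames[1:3], frames[4:6]), s)
  expect_equal(nested$residues, contact_residue_census(frames, s)$residues)
})

test_that("hydrogen bonds implement the distance and angle criteria", {
  # collinear D-H...A with |D-A| = 0.30 nm: angle 180 > 135 -> bond
  atoms <- data.frame(
    name = c("CA", "N", "H", "O1"), element = c("C", "N", "H", "O"),
    resid = c(1L, 1L, 1L, 2L), resname = c("GLY", "GLY", "GLY", "LIG"),
    chain = "A",
    x = c(-0.5, 0, 0.1, 0.3), y = 0, z = 0, occ = 1,
    is_ligand = c(FALSE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  s <- pdb_structure(atoms)
  hb <- hydrogen_bonds(s, donors = 2L, hydrogens = 3L, acceptors = 4L)
  expect_equal(hb$count, 1)
  # |D-A| = 0.36 nm: no bond regardless of angle
  s2 <- s; s2$atoms$x[4] <- 0.36
  expect_equal(hydrogen_bonds(s2, 2L, 3L, 4L)$count, 0)
  # bent geometry below the angle cutoff: angle at H of 90 degrees
  s3 <- s; s3$atoms$x[4] <- 0.1; s3$atoms$y[4] <- 0.2
  expect_equal(hydrogen_bonds(s3, 2L, 3L, 4L)$count, 0)
  # raising angle_min can only lose bonds
  expect_lte(hydrogen_bonds(s, 2L, 3L, 4L, angle_min = 170)$count,
             hb$count)
})

test_that("hydrogen bonds equal the brute-force triple enumeration", {
  for (seed in 1:12) {
    s <- random_structure(n_res = 6, seed = 500 + seed)
    frame <- coords(s) * 0.4  # compress to get some close approaches
    pol <- find_polar_hydrogens(s, frame = frame)
    got <- hydrogen_bonds(s, pol$donors, pol$hydrogens, pol$acceptors,
                          frame = frame)
    want <- oracle_hbonds(s, frame, pol$donors, pol$hydrogens,
                          pol$acceptors)
    expect_equal(got$count, want, label = paste("seed", seed))
  }
})

test_that("binning by displacement averages per bin and flags empty bins", {
  edges <- seq(0, 1, by = 0.25)
  prof <- bin_by_displacement(c(1, 2, 4), c(0.1, 0.3, 0.9), edges)
  expect_equal(prof$mean, c(1, 2, NA, 4))
  expect_equal(prof$n, c(1, 1, 0, 1))
  # all frames in one bin -> mean of all
  p2 <- bin_by_displacement(c(1, 5), c(0.1, 0.2), edges)
  expect_equal(p2$mean[1], 3)
  # weighted mean of bin means equals the global mean
  set.seed(90)
  m <- stats::runif(200); d <- stats::runif(200, 0, 0.999)
  p3 <- bin_by_displacement(m, d, edges)
  expect_equal(sum(p3$mean * p3$n, na.rm = TRUE) / sum(p3$n), mean(m),
               tolerance = 1e-12)
})

test_that("interaction energy matches the single-pair closed form", {
  atoms <- data.frame(
    name = c("CA", "C1"), element = "C", resid = c(1L, 2L),
    resname = c("GLY", "LIG"), chain = "A",
    x = c(0, 0.35), y = 0, z = 0, occ = 1,
    is_ligand = c(FALSE, TRUE), stringsAsFactors = FALSE)
  s <- pdb_structure(atoms)
  par <- data.frame(charge = c(0.5, 0.5), sigma = c(0.3, 0.3),
                    epsilon = c(0.5, 0.5))
  ie <- interaction_energy(s, par)
  # hand-evaluated: LB gives sigma 0.3, eps 0.5 at r = 0.35
  sr6 <- (0.3 / 0.35)^6
  v_lj <- 4 * 0.5 * (sr6^2 - sr6)
  v_c <- 138.935458 * 0.25 / 0.35
  expect_equal(ie$V_LJ, v_lj / 4.184, tolerance = 1e-10)
  expect_equal(ie$V_Coul, v_c / 4.184, tolerance = 1e-10)
  expect_equal(ie$IE, (v_lj + v_c) / 4.184, tolerance = 1e-10)
  # zero parameters -> zero energy
  par0 <- data.frame(charge = 0, sigma = c(0.3, 0.3), epsilon = 0)
  expect_equal(interaction_energy(s, par0)$IE, 0)
  # pair exactly at the cutoff is excluded
  s2 <- s; s2$atoms$x[2] <- 1.0
  expect_equal(interaction_energy(s2, par)$IE, 0)
  # missing parameters are reported with the atom index
  parNA <- par; parNA$sigma[2] <- NA
  expect_error(interaction_energy(s, parNA), "atom")
})

test_that("interaction energy is invariant under rigid motions", {
  s <- random_structure(n_res = 6, seed = 600)
  n <- nrow(s$atoms)
  par <- data.frame(charge = stats::rnorm(n, 0, 0.2),
                    sigma = stats::runif(n, 0.25, 0.4),
                    epsilon = stats::runif(n, 0.1, 1))
  base <- interaction_energy(s, par)
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(coords(s) %*% t(R), 2, c(2, -1, 0.5), "+")
  rot <- interaction_energy(s, par, frame = moved)
  expect_equal(rot$IE, base$IE, tolerance = 1e-9)
})

test_that("potential length finds the stable zero of the IE profile", {
  edges <- seq(0, 2, by = 0.25)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  # step profile vanishing beyond 0.5 nm
  ie <- ifelse(mids < 0.5, -8, 0)
  prof <- bin_by_displacement(ie, mids, edges)
  expect_equal(potential_length(prof), mids[3])
  # identically zero -> first bin center
  prof0 <- bin_by_displacement(rep(0, length(mids)), mids, edges)
  expect_equal(potential_length(prof0), mids[1])
  # re-entrant profile: a later excursion pushes L0 outward
  ie2 <- c(-8, -0.1, -3, -0.2, 0, 0, 0, 0)
  prof2 <- bin_by_displacement(ie2, mids, edges)
  expect_equal(potential_length(prof2), mids[4])
  # never decays -> NA with warning
  prof3 <- bin_by_displacement(rep(-5, length(mids)), mids, edges)
  expect_warning(l <- potential_length(prof3), "never")
  expect_true(is.na(l))
})
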