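# Restraint builder: axis alignment, the six selection modes, index and
# position-restraint files.

test_that("align_pull_axis_to_z maps the axis to +Z and preserves distances", {
  s <- random_structure(n_res = 8, seed = 2)
  # identity case
  al <- align_pull_axis_to_z(s, pull_axis(c(0, 0, 1)))
  expect_equal(al$frame$matrix, diag(3), tolerance = 1e-12)
  # x-axis case
  al <- align_pull_axis_to_z(s, pull_axis(c(1, 0, 0)))
  expect_equal(as.numeric(al$frame$matrix %*% c(1, 0, 0)), c(0, 0, 1),
               tolerance = 1e-12)
  # random directions: rotation is proper and distances survive
  set.seed(9)
  for (rep in 1:8) {
    d <- stats::rnorm(3)
    al <- align_pull_axis_to_z(s, pull_axis(d))
    R <- al$frame$matrix
    expect_equal(R %*% t(R), diag(3), tolerance = 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
    expect_equal(as.numeric(R %*% (d / sqrt(sum(d^2)))), c(0, 0, 1),
                 tolerance = 1e-9)
    x0 <- coords(s); x1 <- coords(al$structure)
    i <- sample(nrow(x0), 10); j <- sample(nrow(x0), 10)
    d0 <- sqrt(rowSums((x0[i, ] - x0[j, ])^2))
    d1 <- sqrt(rowSums((x1[i, ] - x1[j, ])^2))
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
  expect_error(pull_axis(c(0, 0, 0)), "non-zero")
})

test_that("axis-aligned grid fixtures select exactly the forced atoms", {
  # ligand at origin; CA beads on the axis at z = 0.5 and 1.5 nm
  atoms <- data.frame(
    name = c("CA", "CA", "C1"), element = c("C", "C", "C"),
    resid = c(1L, 2L, 3L), resname = c("GLY", "GLY", "LIG"), chain = "A",
    x = 0, y = 0, z = c(0.5, 1.5, 0), occ = 1,
    is_ligand = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  s <- pdb_structure(atoms)
  expect_equal(select_mode(s, 4), 2L)           # only z = 1.5 passes 1.2
  expect_length(select_mode(s, 6), 0)           # 1.8 nm cutoff: none
  expect_equal(select_mode(s, 5), 2L)           # on-axis => radial 0 < 1.2
})

test_that("every mode equals its brute-force oracle on random structures", {
  for (seed in 1:25) {
    s <- random_structure(n_res = 6 + seed %% 6, seed = 100 + seed)
    for (mode in 1:6)
      expect_identical(select_mode(s, mode), oracle_select_mode(s, mode),
                       label = sprintf("seed %d mode %d", seed, mode))
  }
})

test_that("mode selections nest and respond monotonically to cutoffs", {
  sys <- build_toy_system()
  s <- sys$structure
  sel <- lapply(1:6, function(m) select_mode(s, m))
  expect_true(all(sel[[3]] %in% sel[[2]]))
  expect_true(all(sel[[2]] %in% sel[[1]]))
  expect_true(all(sel[[5]] %in% sel[[4]]))
  expect_true(all(sel[[6]] %in% sel[[5]]))
  # counts strictly decrease on the default toy geometry
  expect_true(all(diff(lengths(sel)) < 0))
  # larger axial cutoff never enlarges modes 4-6; larger radial never
  # shrinks modes 5-6
  for (m in 4:6) {
    a <- select_mode(s, m, d_axial = 1.0)
    b <- select_mode(s, m, d_axial = 1.6)
    expect_true(all(b %in% a))
  }
  for (m in 5:6) {
    a <- select_mode(s, m, d_radial = 0.8)
    b <- select_mode(s, m, d_radial = 1.6)
    expect_true(all(a %in% b))
  }
  expect_error(select_mode(s, 7), "unknown")
})

test_that("selections are invariant under translation and Z-rotation", {
  s <- random_structure(n_res = 10, seed = 42)
  shift <- function(s, v) {
    s$atoms$x <- s$atoms$x + v[1]
    s$atoms$y <- s$atoms$y + v[2]
    s$atoms$z <- s$atoms$z + v[3]
    s
  }
  rotz <- function(s, th) {
    x <- s$atoms$x; y <- s$atoms$y
    s$atoms$x <- cos(th) * x - sin(th) * y
    s$atoms$y <- sin(th) * x + cos(th) * y
    s
  }
  roty <- function(s, th) {
    x <- s$atoms$x; z <- s$atoms$z
    s$atoms$x <- cos(th) * x + sin(th) * z
    s$atoms$z <- -sin(th) * x + cos(th) * z
    s
  }
  for (mode in 1:6) {
    expect_identical(select_mode(shift(s, c(1.3, -2.1, 0.7)), mode),
                     select_mode(s, mode))
    expect_identical(select_mode(rotz(s, 1.1), mode), select_mode(s, mode))
  }
  # mode 3 (3-D distance) is invariant under any rotation
  expect_identical(select_mode(roty(s, 0.8), 3), select_mode(s, 3))
})

test_that("index groups convert to 1-based, wrap at 15 per line, round-trip", {
  path <- tempfile(fileext = ".ndx")
  write_index_group(c(1L, 2L, 3L), "trio", path)
  txt <- readLines(path)
  expect_equal(txt[1], "[ trio ]")
  expect_equal(scan(text = txt[2], quiet = TRUE), c(1, 2, 3))
  big <- sort(sample(1000, 298))
  write_index_group(big, "mode2", path)
  lines <- readLines(path)[-1]
  expect_true(all(lengths(strsplit(trimws(lines), "\\s+")) <= 15))
  back <- read_index_group(path, "mode2")
  expect_identical(back, big)
  expect_false(any(duplicated(back)))
  expect_error(write_index_group(integer(0), "empty", path), "empty")
})

test_that("position-restraint files carry (index, k) exactly and nest by mode", {
  path <- tempfile(fileext = ".itp")
  write_position_restraints(1L, 1000, path)
  d <- read_position_restraints(path)
  expect_equal(unname(unlist(d[1, ])), c(1, 1, 1000, 1000, 1000))
  s <- build_toy_system()$structure
  m1 <- select_mode(s, 1); m2 <- select_mode(s, 2)
  p1 <- tempfile(); p2 <- tempfile()
  write_position_restraints(m1, 1000, p1)
  write_position_restraints(m2, 1000, p2)
  expect_gte(nrow(read_position_restraints(p1)),
             nrow(read_position_restraints(p2)))
  expect_identical(read_position_restraints(p1)$index, m1)
  expect_error(write_position_restraints(1L, -5, path), "positive")
})

test_that("build_restraints validates parameters and records the selection", {
  s <- build_toy_system()$structure
  spec <- build_restraints(s, 3)
  expect_s3_class(spec, "restraint_spec")
  expect_identical(spec$selected, select_mode(s, 3))
  expect_equal(spec$d_axial, 1.2)
  spec6 <- build_restraints(s, 6)
  expect_equal(spec6$d_axial, 1.8)
  expect_error(build_restraints(s, 3, force_constant = 0), "positive")
})
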