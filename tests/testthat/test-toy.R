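# Toy pulling simulator: system construction, dynamics limits,
# reproducibility, ensemble generation, mode masks, drift pathology.

test_that("toy system construction is deterministic with an oracle bond list", {
  cfg <- toy_config()
  a <- build_toy_system(cfg)
  b <- build_toy_system(cfg)
  expect_identical(a$bead_xyz, b$bead_xyz)
  expect_identical(a$bonds, b$bonds)
  # brute-force pair scan within the cutoff
  xyz <- a$bead_xyz
  want <- list()
  for (i in seq_len(nrow(xyz) - 1)) for (j in (i + 1):nrow(xyz)) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cfg$net_cutoff)
      want[[length(want) + 1]] <- c(i, j)
  }
  want <- do.call(rbind, want)
  got <- a$bonds[order(a$bonds[, 1], a$bonds[, 2]), , drop = FALSE]
  dimnames(got) <- NULL
  expect_equal(got, want[order(want[, 1], want[, 2]), ])
})

test_that("a single-bead receptor makes a single Morse pair; overlap errors", {
  cfg <- fast_toy_config()
  st <- toy_system(matrix(c(0, 0, -0.6), 1, 3), "CA", c(0, 0, 0), cfg,
                   morse_idx = 1L)
  expect_equal(length(st$morse_idx), 1)
  expect_equal(nrow(st$bonds), 0)
  expect_error(
    toy_system(matrix(c(0, 0, 0.05), 1, 3), "CA", c(0, 0, 0), cfg),
    "overlaps")
})

test_that("frozen ligand gives exactly the linear force ramp", {
  cfg <- toy_config(duration = 500, frame_every = 0, morse_depth = 0)
  st <- toy_system(matrix(0, 0, 3), character(0), c(0, 0, 0), cfg)
  tr <- run_pull(st, freeze_ligand = TRUE)$trace
  expect_equal(tr$force, cfg$k_spring * (cfg$v / 1000) * tr$time,
               tolerance = 1e-12)
  expect_true(all(tr$displacement == 0))
})

test_that("T = 0 free ligand settles to the terminal-velocity force gamma*v", {
  cfg <- toy_config(duration = 200, frame_every = 0, morse_depth = 0,
                    temperature = 0)
  st <- toy_system(matrix(0, 0, 3), character(0), c(0, 0, 0), cfg)
  tr <- run_pull(st)$trace
  expected <- cfg$gamma * cfg$v / 1000
  n <- length(tr$force)
  expect_lt(abs(tr$force[n] - expected) / expected, 1e-6)
  # monotone approach from below
  expect_true(all(diff(tr$force[1:1000]) > 0))
})

test_that("trajectories are bit-identical per (seed, stream)", {
  cfg <- fast_toy_config()
  sys <- build_toy_system(cfg)
  mask <- make_mode_masks(sys, 2)
  a <- run_pull(sys, mask, seed = 33, stream = 4)
  b <- run_pull(sys, mask, seed = 33, stream = 4)
  expect_identical(a$trace$force, b$trace$force)
  expect_identical(a$final, b$final)
  c <- run_pull(sys, mask, seed = 33, stream = 5)
  expect_false(identical(a$trace$force, c$trace$force))
})

test_that("mode masks cover all beads for mode 1, nest, and shrink", {
  sys <- build_toy_system()
  m <- lapply(1:6, make_mode_masks, system = sys)
  expect_equal(sort(m[[1]]), seq_len(nrow(sys$bead_xyz)))
  expect_true(all(m[[6]] %in% m[[5]]))
  expect_true(all(m[[5]] %in% m[[4]]))
  expect_true(all(diff(lengths(m)) < 0))
})

test_that("generate_ensemble derives distinct streams and reproduces itself", {
  cfg <- fast_toy_config()
  sys <- build_toy_system(cfg)
  mask <- make_mode_masks(sys, 1)
  ens1 <- generate_ensemble(cfg, n = 1, mask = mask, seed = 9, system = sys)
  direct <- run_pull(sys, mask, seed = 9, stream = 0)
  expect_identical(ens1$ensemble$traces[[1]]$force, direct$trace$force)
  ens <- generate_ensemble(cfg, n = 5, mask = mask, seed = 9, system = sys)
  fmax <- vapply(ens$ensemble$traces, function(t) rupture_force(t)$fmax, 0)
  expect_equal(length(unique(fmax)), 5)
  ens_b <- generate_ensemble(cfg, n = 5, mask = mask, seed = 9, system = sys)
  expect_identical(fmax,
                   vapply(ens_b$ensemble$traces,
                          function(t) rupture_force(t)$fmax, 0))
})

test_that("ensemble files round-trip through the XVG reader", {
  cfg <- fast_toy_config()
  sys <- build_toy_system(cfg)
  out <- tempfile()
  ens <- generate_ensemble(cfg, n = 2, mask = make_mode_masks(sys, 1),
                           seed = 3, system = sys, out_dir = out)
  tr <- read_pull_trace(file.path(out, "force_001.xvg"),
                        file.path(out, "position_001.xvg"),
                        v = cfg$v, k = cfg$k_spring)
  orig <- ens$ensemble$traces[[1]]
  expect_equal(tr$time, orig$time, tolerance = 1e-9)
  expect_equal(tr$force, orig$force, tolerance = 1e-8)
  expect_equal(tr$displacement, orig$displacement, tolerance = 1e-8)
})

test_that("rupture-force SE shrinks roughly as 1/sqrt(N)", {
  cfg <- toy_config(duration = 1000, record_every = 10, frame_every = 0)
  sys <- build_toy_system(cfg)
  mask <- make_mode_masks(sys, 2)
  ens <- generate_ensemble(cfg, n = 60, mask = mask, seed = 17,
                           system = sys)
  fmax <- vapply(ens$ensemble$traces, function(t) rupture_force(t)$fmax, 0)
  se <- function(x) sd(x) / sqrt(length(x))
  ratio <- se(fmax[1:15]) / se(fmax)
  expect_gt(ratio, 1.1)   # ~2 expected for iid samples
  expect_lt(ratio, 3.6)
})

test_that("unrestrained receptor with no network drifts more than mode 1", {
  drift <- function(mask, seed, k_net) {
    cfg <- toy_config(duration = 400, record_every = 20, frame_every = 0,
                      k_net = k_net)
    sys <- build_toy_system(cfg)
    fin <- run_pull(sys, mask, seed = seed)$final
    nb <- nrow(sys$bead_xyz)
    sqrt(sum((colMeans(fin[seq_len(nb), ]) - colMeans(sys$bead_xyz))^2))
  }
  sys0 <- build_toy_system(toy_config())
  all_beads <- seq_len(nrow(sys0$bead_xyz))
  few <- make_mode_masks(sys0, 6)
  wins <- vapply(1:20, function(s)
    drift(few, s, k_net = 0) > drift(all_beads, s, k_net = 100), TRUE)
  # sign test at p < 0.01: at least 15 of 20
  expect_gte(sum(wins), 15)
})

test_that("numerical blow-up is reported with the step index", {
  cfg <- toy_config(duration = 2500, frame_every = 0, box_bound = 1,
                    morse_depth = 0)
  st <- toy_system(matrix(0, 0, 3), character(0), c(0, 0, 0), cfg)
  expect_error(run_pull(st), "blow-up at step")
})
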