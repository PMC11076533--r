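# Coarse-grained toy pulling simulator.
#
# The receptor is a bead network: a pocket of beads on the lower
# hemisphere of a shell around the ligand (the binding site), a lateral
# ring, and deeper bead layers that give the six restraint modes strictly
# decreasing selection counts on the default geometry. Beads interact
# through an elastic network (harmonic springs between beads within a
# cutoff), the ligand binds the pocket beads through Morse pairs, and a
# harmonic spring whose anchor moves at constant velocity pulls the ligand
# along +Z. Dynamics are overdamped Langevin: friction plus noise stand in
# for the solvent bath. Beads in the restraint mask are tethered
# harmonically to their initial positions, exactly like position
# restraints in an MD engine.

#' Configuration for the toy pulling simulator
#'
#' Defaults mirror the pulling protocol the analysis targets: pulling
#' velocity 1.0 nm/ns, spring constant 600 kJ/mol/nm^2, 3 ns duration,
#' force/displacement recorded every 10 fs, coordinate frames every 10 ps
#' (300 frames per trajectory), 300 K.
#'
#' @param pocket_radius radius of the binding-pocket bead cup, nm.
#' @param n_pocket number of C-alpha beads on the pocket cup (lower
#'   hemisphere below the ligand).
#' @param n_gate number of C-alpha beads on the exit-gate ring above the
#'   ligand; their repulsive cores block the exit path when restrained and
#'   swing aside when free.
#' @param gate_radius cylinder radius of the gate ring, nm.
#' @param n_pocket_side number of non-C-alpha heavy beads near the pocket
#'   (they distinguish the all-heavy-atom mode from the all-C-alpha mode).
#' @param k_net elastic-network spring constant, kJ/mol/nm^2.
#' @param net_cutoff elastic-network bond cutoff, nm.
#' @param morse_depth per-pair ligand-pocket Morse well depth, kcal/mol.
#' @param morse_a Morse width parameter, 1/nm.
#' @param k_restraint position-restraint force constant, kJ/mol/nm^2.
#' @param k_spring pulling spring constant, kJ/mol/nm^2.
#' @param v pulling velocity, nm/ns.
#' @param temperature kelvin.
#' @param gamma friction coefficient, kJ mol^-1 ps nm^-2.
#' @param dt integration timestep, ps (default 10 fs).
#' @param duration trajectory length, ps (default 3 ns).
#' @param record_every record force/displacement every this many steps.
#' @param frame_every save a coordinate frame every this many steps
#'   (0 = no frames).
#' @param box_bound blow-up guard: error if any coordinate exceeds, nm.
#' @param seed master seed (non-negative integer).
#' @return list of class `toy_config`.
#' @export
toy_config <- function(pocket_radius = 0.6, n_pocket = 12, n_gate = 6,
                       gate_radius = 0.4,
                       n_pocket_side = 6, k_net = 100, net_cutoff = 1.1,
                       morse_depth = 5, morse_a = 8,
                       k_restraint = 1000, k_spring = 600, v = 1.0,
                       temperature = 300, gamma = 2500, dt = 0.01,
                       duration = 3000, record_every = 1,
                       frame_every = 1000, box_bound = 50, seed = 1) {
  stopifnot(pocket_radius > 0, morse_a > 0, gamma > 0, dt > 0,
            duration > 0, k_spring >= 0, k_restraint >= 0, k_net >= 0,
            morse_depth >= 0, temperature >= 0, record_every >= 1,
            frame_every >= 0, seed >= 0)
  cfg <- list(pocket_radius = pocket_radius, n_pocket = n_pocket,
              n_gate = n_gate, gate_radius = gate_radius,
              n_pocket_side = n_pocket_side, k_net = k_net,
              net_cutoff = net_cutoff, morse_depth = morse_depth,
              morse_a = morse_a, k_restraint = k_restraint,
              k_spring = k_spring, v = v, temperature = temperature,
              gamma = gamma, dt = dt, duration = duration,
              record_every = record_every, frame_every = frame_every,
              box_bound = box_bound, seed = as.integer(seed))
  class(cfg) <- "toy_config"
  cfg
}

# deterministic points on the lower hemisphere of a shell (golden spiral)
.hemisphere_points <- function(n, radius, phase = 0) {
  if (n == 0) return(matrix(0, 0, 3))
  i <- seq_len(n)
  z <- -(i - 0.5) / n                 # in (-1, 0)
  phi <- i * pi * (3 - sqrt(5)) + phase
  r <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(r * cos(phi), r * sin(phi), z)
}

# ring of points at a given cylinder radius and depth
.ring_points <- function(n, radius, z, phase = 0) {
  if (n == 0) return(matrix(0, 0, 3))
  phi <- 2 * pi * seq_len(n) / n + phase
  cbind(radius * cos(phi), radius * sin(phi), rep(z, n))
}

#' Assemble a toy system from explicit bead coordinates
#'
#' Low-level constructor used by [build_toy_system()]; also handy for
#' minimal systems (a single tethered bead, a bare dragged ligand).
#' Builds the elastic-network bond list (bead pairs within the cutoff),
#' the Morse pair list, and (when beads exist) a [pdb_structure] view of
#' the beads so the restraint-mode selector can run on the toy receptor.
#'
#' @param bead_xyz n x 3 matrix of bead positions, nm (may have 0 rows).
#' @param bead_names atom names for the beads ("CA" beads are treated as
#'   alpha-carbons by the mode selector, anything else as generic heavy
#'   atoms).
#' @param ligand_xyz length-3 ligand position, nm.
#' @param config a [toy_config].
#' @param morse_idx bead indices (1-based) bound to the ligand by Morse
#'   pairs.
#' @return list of class `toy_system`.
#' @export
toy_system <- function(bead_xyz, bead_names, ligand_xyz, config,
                       morse_idx = integer(0)) {
  bead_xyz <- matrix(as.numeric(bead_xyz), ncol = 3)
  n <- nrow(bead_xyz)
  if (length(bead_names) != n) stop("one name per bead required")
  if (n > 0) {
    d2 <- .pair_dist2(bead_xyz, matrix(ligand_xyz, 1, 3))
    if (min(d2) < 0.1^2)
      stop("ligand overlaps a receptor bead (< 0.1 nm)")
  }
  bonds <- matrix(integer(0), 0, 2)
  r0 <- numeric(0)
  if (n >= 2) {
    d2 <- .pair_dist2(bead_xyz, bead_xyz)
    hit <- which(d2 < config$net_cutoff^2, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    bonds <- hit
    r0 <- sqrt(d2[hit])
  }
  struct <- NULL
  if (n > 0) {
    atoms <- data.frame(
      name = bead_names, element = "C", resid = seq_len(n),
      resname = "BEA", chain = "A",
      x = bead_xyz[, 1], y = bead_xyz[, 2], z = bead_xyz[, 3],
      occ = 1, is_ligand = FALSE, stringsAsFactors = FALSE)
    lig <- data.frame(name = "C1", element = "C", resid = n + 1L,
                      resname = "LIG", chain = "A",
                      x = ligand_xyz[1], y = ligand_xyz[2],
                      z = ligand_xyz[3], occ = 1, is_ligand = TRUE,
                      stringsAsFactors = FALSE)
    if (any(bead_names == "CA"))
      struct <- pdb_structure(rbind(atoms, lig),
                              ligand_selector = list(resname = "LIG"))
  }
  structure(list(bead_xyz = bead_xyz, bead_names = bead_names,
                 ligand_xyz = as.numeric(ligand_xyz),
                 bonds = bonds, bond_r0 = r0, morse_idx = morse_idx,
                 structure = struct, config = config),
            class = "toy_system")
}

#' Build the default toy receptor-ligand system
#'
#' The geometry places, around a ligand bead at the origin:
#' pocket C-alpha beads on the lower hemisphere of the pocket shell plus a
#' few non-C-alpha heavy beads just outside it (Morse-bound to the
#' ligand), a lateral ring (far in 3-D but level with the ligand), a deep
#' off-axis layer, and two on-axis columns at depths chosen so the six
#' restraint modes select strictly decreasing bead counts. Deterministic
#' given the configuration.
#'
#' @param config a [toy_config].
#' @return A `toy_system`.
#' @export
build_toy_system <- function(config = toy_config()) {
  R <- config$pocket_radius
  cup <- .hemisphere_points(config$n_pocket, R)
  gate <- .ring_points(config$n_gate, config$gate_radius, 0.5 * R)
  side <- .hemisphere_points(config$n_pocket_side, 1.25 * R, phase = 1.3)
  ring <- .ring_points(10, 1.6, -0.3)
  deep_off <- .ring_points(8, 1.5, -1.5, phase = 0.4)
  mid_col <- .ring_points(8, 0.6, -1.45, phase = 0.2)
  deep_col <- .ring_points(6, 0.6, -2.0, phase = 0.9)
  bead_xyz <- rbind(cup, gate, side, ring, deep_off, mid_col, deep_col)
  bead_names <- c(rep("CA", config$n_pocket + config$n_gate),
                  rep("C", config$n_pocket_side),
                  rep("CA", nrow(ring) + nrow(deep_off) + nrow(mid_col) +
                        nrow(deep_col)))
  morse_idx <- seq_len(config$n_pocket + config$n_gate)
  toy_system(bead_xyz, bead_names, c(0, 0, 0), config,
             morse_idx = morse_idx)
}

#' @export
print.toy_system <- function(x, ...) {
  cat("toy_system:", nrow(x$bead_xyz), "receptor beads (",
      sum(x$bead_names == "CA"), "CA ),", nrow(x$bonds),
      "network bonds,", length(x$morse_idx), "Morse pairs\n")
  invisible(x)
}

#' Restraint mask for a toy system under a given mode
#'
#' Runs the restraint-mode selector on the bead structure (beads named
#' "CA" act as alpha-carbons, all beads as heavy atoms) and maps the
#' selection back to bead indices. The default geometry yields strictly
#' decreasing mask sizes from mode 1 to mode 6 with the standard cutoffs.
#'
#' @param system a `toy_system` built from C-alpha-named beads.
#' @param mode integer 1-6.
#' @param ... passed to [select_mode()] (cutoffs, reference).
#' @return integer vector of bead indices to restrain.
#' @export
make_mode_masks <- function(system, mode, ...) {
  if (is.null(system$structure))
    stop("toy system has no C-alpha beads; cannot build mode masks")
  sel <- select_mode(system$structure, mode, ...)
  sel[sel <= nrow(system$bead_xyz)]
}

#' Run one toy pulling trajectory
#'
#' Overdamped Langevin dynamics: masked beads are tethered to their
#' initial positions with `k_restraint`, the ligand feels the Morse
#' binding and the constant-velocity pulling spring along +Z, and the
#' recorded force is the spring force. Bit-reproducible for a given
#' (seed, stream) pair on any platform.
#'
#' @param system a `toy_system`.
#' @param mask bead indices (1-based) to restrain.
#' @param seed non-negative integer seed.
#' @param stream trajectory index within an ensemble (default 0); the
#'   per-trajectory generator state is derived from (seed, stream) by a
#'   fixed splitmix-style mixing function.
#' @param freeze_ligand hold the ligand fixed (infinite-restraint limit;
#'   the recorded force then grows exactly linearly in time).
#' @return list of class `toy_trajectory`: `trace` (a [pull_trace]),
#'   `frames` (list of (n+1) x 3 coordinate matrices, ligand last),
#'   `final` coordinates, `seed`, `stream`, `config`.
#' @export
run_pull <- function(system, mask = integer(0), seed = system$config$seed,
                     stream = 0, freeze_ligand = FALSE) {
  cfg <- system$config
  n_steps <- round(cfg$duration / cfg$dt)
  out <- .cpp_run_pull(
    system$bead_xyz, system$ligand_xyz,
    matrix(as.integer(system$bonds - 1L), ncol = 2), system$bond_r0,
    cfg$k_net, as.integer(system$morse_idx - 1L),
    cfg$morse_depth * rk_constants$kJ_per_kcal, cfg$morse_a,
    cfg$pocket_radius, as.integer(mask - 1L), cfg$k_restraint,
    cfg$k_spring, cfg$v / 1000, cfg$gamma,
    rk_constants$kB_kJ * cfg$temperature, cfg$dt, as.integer(n_steps),
    as.integer(cfg$record_every), as.integer(cfg$frame_every),
    freeze_ligand, cfg$box_bound, as.integer(seed), as.integer(stream))
  trace <- pull_trace(out$time, out$force, out$displacement,
                      v = cfg$v, k = cfg$k_spring)
  structure(list(trace = trace, frames = out$frames, final = out$final,
                 seed = seed, stream = stream, config = cfg),
            class = "toy_trajectory")
}

#' @export
print.toy_trajectory <- function(x, ...) {
  cat("toy_trajectory (seed", x$seed, ", stream", x$stream, ")\n")
  print(x$trace)
  invisible(x)
}

#' Generate an ensemble of toy pulling trajectories
#'
#' Runs `n` independent trajectories whose generator streams are derived
#' from the master seed, optionally writing XVG-style force/position files
#' (the same format [read_pull_trace()] consumes) and returning the
#' coordinate frames needed by the contact/interaction analyses.
#'
#' @param config a [toy_config].
#' @param n number of trajectories.
#' @param mask restrained bead indices, e.g. from [make_mode_masks()].
#' @param seed master seed (default from config).
#' @param system optional pre-built `toy_system` (default
#'   [build_toy_system()]).
#' @param mode optional mode label attached to the ensemble.
#' @param keep_frames keep coordinate frames in memory.
#' @param out_dir if non-NULL, write `force_NNN.xvg` / `position_NNN.xvg`
#'   per trajectory into this directory.
#' @return list of class `toy_ensemble`: `ensemble` (a [pull_ensemble]),
#'   `frames` (list per trajectory, or NULL), `system`, `config`, `seed`.
#' @export
generate_ensemble <- function(config = toy_config(), n = 100,
                              mask = integer(0), seed = config$seed,
                              system = NULL, mode = NA,
                              keep_frames = FALSE, out_dir = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(system)) system <- build_toy_system(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  traces <- vector("list", n)
  frames <- if (keep_frames) vector("list", n) else NULL
  for (i in seq_len(n)) {
    tr <- run_pull(system, mask = mask, seed = seed, stream = i - 1L)
    traces[[i]] <- tr$trace
    if (keep_frames) frames[[i]] <- tr$frames
    if (!is.null(out_dir)) {
      write_xvg(tr$trace$time, tr$trace$force,
                file.path(out_dir, sprintf("force_%03d.xvg", i)),
                title = sprintf("toy pull force, seed %d stream %d",
                                seed, i - 1L))
      write_xvg(tr$trace$time, tr$trace$displacement,
                file.path(out_dir, sprintf("position_%03d.xvg", i)),
                title = sprintf("toy ligand displacement, seed %d stream %d",
                                seed, i - 1L))
    }
  }
  structure(list(ensemble = pull_ensemble(traces, mode = mode),
                 frames = frames, system = system, config = config,
                 seed = seed, mask = mask),
            class = "toy_ensemble")
}

#' Non-bonded parameter table for a toy system
#'
#' The toy simulator carries no force-field topology; this supplies a
#' minimal Lennard-Jones parameter set (uncharged beads) so the
#' interaction-energy machinery can run on toy frames. One row per
#' particle, ligand last, matching the toy structure's atom order.
#'
#' @param system a `toy_system`.
#' @param sigma LJ sigma, nm.
#' @param epsilon LJ epsilon, kJ/mol.
#' @param charge partial charge, e.
#' @return data.frame with columns `charge`, `sigma`, `epsilon`.
#' @export
toy_nonbonded_params <- function(system, sigma = 0.45, epsilon = 2,
                                 charge = 0) {
  n <- nrow(system$bead_xyz) + 1L
  data.frame(charge = rep(charge, n), sigma = rep(sigma, n),
             epsilon = rep(epsilon, n))
}

#' @export
print.toy_ensemble <- function(x, ...) {
  cat("toy_ensemble: mask of", length(x$mask), "restrained beads\n")
  print(x$ensemble)
  invisible(x)
}
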