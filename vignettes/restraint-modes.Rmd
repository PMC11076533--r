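---
title: "Restraint modes and pulling-ensemble analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint modes and pulling-ensemble analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Constant-velocity steered molecular dynamics (SMD) pulls a bound ligand
out of its receptor with a harmonic spring whose anchor moves at speed
$v$ along a chosen unbinding direction. The recorded spring force
$F(t) = k\,(vt - z(t))$ rises until the ligand–receptor contacts rupture;
its maximum $F_{\max}$ and the external work $W = v\!\int\!F\,\mathrm{d}t$
are the quantities usually compared across ligands. Before pulling, part
of the receptor must be position-restrained so that the pulling force
does not simply translate or spin the whole complex. Which atoms are
restrained is a free choice of the protocol, and this package exists to
make that choice explicit, reproducible, and analysable: it implements
six selection schemes spanning full rigidity to near-full flexibility,
emits machine-usable restraint files, and provides the ensemble analysis
needed to quantify how the choice propagates into rupture forces, works,
free-energy barriers, and the protein–ligand interaction picture.

## The six restraint modes

All cutoff-based modes presuppose that the structure has been rigidly
rotated so the pulling direction is $+Z$ (`align_pull_axis_to_z()`;
Rodrigues rotation, proper orthogonal to $10^{-10}$). With the ligand's
heavy atoms $L$ and a protein $\mathrm{C}\alpha$ atom at $(x,y,z)$:

* **mode 1** — all protein heavy atoms (elements C, N, O, S);
* **mode 2** — all $\mathrm{C}\alpha$ atoms;
* **mode 3** — $\mathrm{C}\alpha$ with $\min_{l \in L} \lVert r - r_l
  \rVert > 1.2$ nm;
* **mode 4** — $\mathrm{C}\alpha$ with $\min_{l \in L} |z - z_l| > 1.2$
  nm (along-axis separation);
* **mode 5** — mode 4 **and** $\min_{l \in L} \sqrt{(x-x_l)^2 +
  (y-y_l)^2} < 1.2$ nm (in-plane radial separation);
* **mode 6** — mode 5 with the along-axis cutoff raised to 1.8 nm.

Design choices worth recording:

* *"Distance to ligand" is the minimum over ligand heavy atoms* by
  default, consistent with the minimum-distance convention used by the
  contact analysis; measuring to the ligand's mass-weighted centre of
  mass is available via `reference = "com"`.
* Modes 5–6 intersect the along-axis and radial conditions. Because
  $|z - z_l| > c$ implies $\lVert r - r_l \rVert > c$, the selections
  nest: mode 4 ⊆ mode 3 ⊆ mode 2 and mode 6 ⊆ mode 5 ⊆ mode 4. This
  intersection reading is the only one consistent with restraint counts
  that decrease monotonically from mode 1 to mode 6.
* Inequalities are strict; an atom exactly at a cutoff is *not* selected
  by a "greater than" condition. The boundary set has measure zero for
  real coordinates, but the tie-break is fixed so emitted files are
  deterministic.
* Atom indices are 1-based throughout (R's native convention), which is
  also what the GROMACS-style `.ndx`/`.itp` formats require, so no
  re-indexing happens at the I/O boundary.
* The default per-axis restraint force constant is 1000 kJ/mol/nm²; the
  literature rarely quantifies "restrained by a small force", so the
  value is configurable and always written into the emitted files.
* Alternate locations in PDB input resolve to the highest-occupancy copy
  (ties: first encountered); crystallographic waters and lone monoatomic
  ions are excluded before any selection. Ligand identification is
  explicit (residue name, optionally chain) — no het-group guessing.

## Ensemble analysis

A pulling trajectory is a `pull_trace`: time (ps), spring force
(kJ/mol/nm; converted to pN with 1 kJ/mol/nm = 1.660539 pN on report) and
ligand-COM displacement (nm, zero at $t=0$). Ensembles of $N$ traces
share $v$ and $k$.

* **Rupture force**: global maximum of the force series, earliest sample
  on ties, no smoothing by default.
* **Pulling work**: $W = v\int F\,\mathrm{d}t$ by the trapezoidal rule,
  reported in kcal/mol (1 kcal = 4.184 kJ). For a frozen ligand
  $F(t) = kvt$ exactly, and the quadrature reproduces
  $W = \tfrac12 k v^2 T^2$ to $10^{-4}$ relative on a 10 fs grid — this
  closed form is the package's primary numerical anchor.
* **Free-energy profile**: per trace, the cumulative work is re-indexed
  from time to a displacement grid; across traces the per-grid-point
  moments give either $G(z) = \langle W(z)\rangle$ (`"mean-work"`) or the
  Jarzynski second-order cumulant
  $G(z) = \langle W(z)\rangle - \mathrm{Var}\,W(z)/2k_BT$
  (`"jarzynski-2nd-cumulant"`, default, $T = 300$ K default). The
  estimator tag travels with the profile; the cumulant is exact for
  Gaussian work distributions and never exceeds the mean-work estimate.
  The **unbinding barrier** is $\max_z G - G(0)$ with $G(0) = 0$ by
  construction.
* **Coordinate for re-indexing**: the default maps work to the *ligand
  displacement* at its first passage of each grid point, matching how
  displacement-resolved observables (hydrogen bonds, interaction energy)
  are plotted. Because the ligand coordinate fluctuates thermally,
  first-passage evaluation conditions on favourable fluctuations and
  biases the work moments by a fraction of $k_BT$ — an indexing
  artifact, not a free-energy error, and it does not shrink with $N$.
  `coordinate = "anchor"` instead indexes by the spring-anchor position
  $vt$ (deterministic; the stiff-spring convention), for which the
  cumulant estimator's exactness on a translated harmonic trap is
  recovered within statistical error. Quantitative estimator checks use
  the anchor coordinate; mode-to-mode comparisons are insensitive to the
  choice.
* **Skew-normal fits** of $F_{\max}$ distributions are maximum-likelihood
  (Nelder–Mead on location, log-scale, shape; method-of-moments start
  from the sample skewness clamped away from the fold at $|\delta| =
  0.95$). Degenerate (zero-variance) samples and $n < 10$ are rejected.
* **RMSD** follows the plain formula
  $\sqrt{\tfrac1N \sum_i |x_i - x_i^{\mathrm{ref}}|^2}$; with
  `fit = TRUE` an optimal rigid superposition (Kabsch via SVD, reflection
  corrected) is applied first, as trajectory-RMSD tools do.

## Interaction metrics

* **Contact**: a (protein heavy atom, ligand atom) pair closer than 0.6
  nm; a frame's contact residues are those contributing at least one
  pair, and the **census** of an ensemble is the union over all frames of
  all trajectories — monotone under adding frames by construction.
* **Hydrogen bond**: donor–acceptor distance < 0.35 nm *and* the angle at
  the hydrogen between donor and acceptor > 135°. The donor–hydrogen
  covalent mapping must be supplied; `find_polar_hydrogens()` infers it
  geometrically (nearest N/O within 0.12 nm) for structures without
  topology. Both directions (protein→ligand and ligand→protein) count.
* **Interaction energy**: a plain pairwise sum over protein–ligand pairs
  within 1.0 nm (strict) of Lennard-Jones 12-6 with Lorentz–Berthelot
  combination and Coulomb $f q_i q_j / \epsilon_r r$,
  $f = 138.935458$ kJ mol⁻¹ nm e⁻². No Ewald/reaction-field long-range
  treatment is attempted, so these values are *not* interchangeable with
  engine-computed energies; they are internally consistent for
  displacement-profile comparisons, which is their only use here.
* **Potential length** $L_0$: the smallest displacement-bin centre where
  $|IE|$ drops below a threshold (default 1 kcal/mol — the zero-crossing
  tolerance is not standardised anywhere, so it is an explicit argument)
  and stays below for all larger displacements; empty bins are skipped,
  and a profile that never decays yields `NA` with a warning rather than
  a fabricated length.

## The toy simulator: what it emulates, and what it does not

`build_toy_system()` constructs a coarse receptor around a single ligand
bead at the origin: a binding **cup** of 12 $\mathrm{C}\alpha$ beads on
the lower hemisphere of a 0.6 nm shell, an exit **gate** ring of 6
$\mathrm{C}\alpha$ beads (cylinder radius 0.4 nm) just above the ligand,
6 non-$\mathrm{C}\alpha$ heavy beads flanking the cup, and lateral/deep
bead layers placed so the six modes select strictly decreasing counts
(56, 50, 32, 22, 14, 6 on the defaults). Beads within 1.1 nm are joined
by harmonic network bonds ($k_{\mathrm{net}} = 100$ kJ/mol/nm² — soft,
so an unrestrained pocket can yield); cup and gate beads bind the ligand
through Morse pairs (depth 5 kcal/mol, width 8 nm⁻¹, minimum at the cup
radius). Dynamics are overdamped Langevin,
$\mathrm{d}x = (F/\gamma)\,\mathrm{d}t + \sqrt{2 k_B T
\Delta t/\gamma}\,\xi$, with $\gamma = 2500$ kJ ps mol⁻¹ nm⁻² (ligand
diffusion $\approx 1$ nm²/ns), $T = 300$ K, 10 fs steps, 3 ns duration,
force/displacement recorded every step and frames every 10 ps (300 per
trajectory) — the pulling protocol itself ($v = 1$ nm/ns, $k = 600$
kJ/mol/nm²) matches the SMD convention the analysis targets. Restrained
beads are tethered harmonically to their initial positions exactly as
engine position restraints are.

The gate is the mechanistically important piece: when the gate beads are
restrained their repulsive Morse cores form a bottleneck the ligand must
be forced through, and when they are free they swing aside at low cost.
This is what makes receptor rigidity *raise* both the rupture force and
the pulling work on the toy — the same direction as in all-atom
studies — rather than merely adding noise. Friction plus noise stand in
for the solvent bath, which also reproduces the known pathology that an
essentially unrestrained receptor drifts under pulling.

Randomness comes from a self-contained splitmix64 generator with
Box–Muller normals, seeded by a fixed mixing of (master seed, trajectory
stream); trajectories are therefore bit-identical across platforms and
independent of R's RNG state.

What the toy does **not** emulate: explicit solvent and hydrodynamics,
atomistic force fields, inertial dynamics, multiple unbinding pathways,
and the absolute magnitudes of any real system — passing toy-based tests
demonstrates that the *analysis machinery* behaves correctly and that the
*qualitative* restraint-mode ordering emerges from the stated mechanism,
not that any particular protein's numbers are reproduced. The toy's mode
1 and mode 2 are also nearly equivalent by construction (the gate and cup
are $\mathrm{C}\alpha$ beads, so both modes restrain them); the large
rigid-vs-flexible contrast lives between modes 1–2 and modes 3–6, and
quantitative checks therefore compare the two extremes, mode 1 and
mode 6.

## Numerical choices and degenerate inputs

* Internal units: nm, ps, kJ/mol; PDB Å are converted on read and
  restored on write (3-decimal Å precision, the format's limit — hence
  the $10^{-4}$ nm round-trip tolerance).
* XVG force/position grids are joined by nearest time with a tolerance of
  half the sampling step; non-monotone time and empty files are errors.
* The Euler–Maruyama step is stable for $k\,\Delta t/\gamma < 2$; the
  stiffest default interaction gives $\approx 0.12$. Coordinates beyond a
  50 nm guard radius abort with the step index (numerical blow-up).
* Equipartition discretisation bias for a tethered bead is
  $2/(2 - k\Delta t/\gamma) - 1 \approx 0.2\%$ at the defaults, well
  inside the 5% tolerance used in the quantitative check.
* Empty atom sets, empty index groups, non-positive force constants,
  missing non-bonded parameters, mismatched frame sizes, and a cumulant
  estimator with one trace are all explicit errors, never silent
  defaults.

## Problem sizes used in the checks

The package's own verification runs at desk scale: 200 trajectories of 1
ns for the translated-trap estimator check, a 30 ns single-bead run for
equipartition, 50 trajectories per arm of 3 ns for the mode-1 vs mode-6
comparison (one-sided Mann–Whitney on $F_{\max}$ and $W$), 20 paired
seeds for the census and $L_0$ sign tests, and ~100+ random fixtures for
the brute-force oracle comparisons. The published-count comparison for
deposited complexes requires the corresponding PDB files, which are not
distributable with the package; `tests/testthat/test-acceptance.R`
documents where to place them (`inst/extdata/real/`).

## Known limitations

* Restraint counts on deposited structures depend on the exact prepared
  coordinates (repaired residues, protonation, pre-equilibration), so
  bit-exact agreement with any published table cannot be guaranteed from
  the raw PDB entry alone.
* The second-cumulant barrier estimate subtracts a variance term that is
  itself noisy at $N \sim 50$ and biased low for strongly dissipative
  (non-Gaussian-work) pulls; both estimators are therefore exposed and
  every profile is labelled with the one that produced it.
* Interaction energies are short-range pairwise sums (no PME), and the
  toy's non-bonded parameter table is a uniform LJ stand-in, adequate for
  displacement profiles and $L_0$ comparisons only.
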