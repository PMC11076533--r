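# restraintkit

Tools for studying how the choice of **position restraints** on a receptor
changes the outcome of **steered molecular dynamics (SMD)** ligand-unbinding
simulations.

In constant-velocity SMD a harmonic spring of stiffness *k* is attached to
the ligand's centre of mass and its anchor is moved along the unbinding
direction at speed *v*; the recorded spring force
*F*(*t*) = *k*(*vt* − *z*(*t*)) peaks at the **rupture force**
*F*<sub>max</sub>, and the external **pulling work** is
*W* = *v* ∫ *F* d*t*. Before pulling, part of the protein must be
harmonically restrained so the complex does not simply drift — but *which*
atoms are restrained is rarely reported and strongly affects every number
downstream. `restraintkit` implements six selection schemes in decreasing
order of rigidity, all cutoffs measured to the ligand after the pulling
axis has been rotated onto +Z:

| mode | restrained set |
|------|----------------|
| 1 | all protein heavy atoms (C, N, O, S) |
| 2 | all Cα atoms |
| 3 | Cα with 3-D distance to ligand > 1.2 nm |
| 4 | Cα with along-axis (Z) distance to ligand > 1.2 nm |
| 5 | mode 4 ∧ in-plane radial distance < 1.2 nm |
| 6 | mode 5 with the along-axis cutoff raised to 1.8 nm |

and the ensemble analysis used to compare them:

* per-trajectory *F*<sub>max</sub> and *W*, ensemble means ± standard
  errors, running-mean convergence, skew-normal fits of the
  *F*<sub>max</sub> distribution;
* free-energy profiles *G*(*z*) along the pulling coordinate from the work
  moments, with two labelled estimators — plain mean work and the
  Jarzynski second-order cumulant
  *G*(*z*) = ⟨*W*(*z*)⟩ − Var *W*(*z*)/2*k*<sub>B</sub>*T* — and the
  **unbinding barrier** ΔG<sup>‡</sup> = max *G* − *G*(0);
* geometric interaction metrics over trajectory frames: contacts
  (minimum-distance < 0.6 nm), hydrogen bonds (donor–acceptor < 0.35 nm and
  D–H···A angle > 135°), contact-residue census, displacement-binned
  interaction-energy profiles (LJ 12-6 + Coulomb within 1.0 nm) and the
  potential length *L*<sub>0</sub> at which the interaction decays to zero;
* RMSD with optional Kabsch superposition.

Because full all-atom SMD needs an MD engine and cluster time, the package
ships a **coarse-grained toy pulling simulator**: an elastic-network bead
receptor with a binding cup and an exit gate, a Morse-bound ligand, and a
moving harmonic spring, integrated with overdamped Langevin dynamics
(bit-reproducible per seed). It emits the same XVG-style force/position
files and multi-model PDB frames the analysis consumes, so the entire
select → simulate → analyse pipeline is testable on a desktop.

## Worked example

Select restraints for a PDB complex and emit GROMACS-style files:

```r
library(restraintkit)
s <- read_pdb("complex.pdb", ligand = "LIG")
s <- align_pull_axis_to_z(s, pull_axis(c(0.3, 0.2, 0.93)))$structure
spec <- build_restraints(s, mode = 2)
write_index_group(spec$selected, "mode2", "restraints.ndx")
write_position_restraints(spec$selected, spec$force_constant, "posre.itp")
```

Run the toy pipeline for the two extreme modes and compare:

```r
rep <- run_pipeline(toy_config(), modes = c(1, 6), n = 10, seed = 42)
print(rep)
```

```
per-mode pulling summary (toy system)
 mode       Fmax (pN) Wpull (kcal/mol) barrier (kcal/mol) RMSD (nm) census
    1 1517.3 +/- 19.7  181.28 +/- 4.67             102.94     0.073     21
    6 1003.6 +/- 12.8  135.89 +/- 2.07             105.53     0.846     34
```

Reading the rows: with every heavy bead restrained (mode 1) the ligand must
squeeze past a rigid exit gate, so the mean rupture force (1517 pN) and
pulling work (181 kcal/mol) are far larger than with the sparsest restraint
set (mode 6: 1004 pN, 136 kcal/mol); the flexible receptor deforms instead
(final backbone RMSD 0.85 nm vs 0.07 nm) and many more beads come into
contact with the ligand during its escape (census 34 vs 21) — the same
qualitative picture reported for real protein–ligand systems.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/restraintkit.R select --pdb complex.pdb --ligand LIG \
        --mode 3 --axis "0 0 1" --out restraints
Rscript inst/cli/restraintkit.R toy --mode 6 --ntraj 100 --seed 7 --out toy_out
Rscript inst/cli/restraintkit.R analyze --forces "toy_out/force_*.xvg" \
        --positions "toy_out/position_*.xvg" --out analysis
```

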