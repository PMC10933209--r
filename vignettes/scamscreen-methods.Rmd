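---
title: "Detecting small-molecule aggregation in MD trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting small-molecule aggregation in MD trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scamscreen)
```

## The screen

Small colloidally aggregating molecules (SCAMs) are a leading source of
false positives in biochemical screens. A physics-based flag for them is to
place 11–12 copies of a compound in a periodic solvent box at millimolar
concentration — well above typical critical aggregation concentrations — and
test whether they spontaneously self-associate over a trajectory. This
package implements the analysis of such trajectories; it does not run
solvated MD itself.

### Cluster definition

In each analysed frame, two solute molecules are joined when *any* atom of
one (heavy or hydrogen) lies within a cutoff distance of any atom of the
other, measured under the minimum-image convention. Clusters are the
connected components of this contact graph — single linkage, so a chain of
pairwise contacts is one cluster. The per-frame cluster count is N\_c,
ranging from 1 (a single aggregate) to N\_mol (fully dispersed).

Parameter choices and their rationale:

* **Cutoff, 3.0 Å (atomistic default).** The smallest value that still
  captures nearest-neighbour contacts between interacting solutes; much
  beyond 5–6 Å the test starts merging molecules that are merely nearby.
  The comparison is inclusive (`<=`), reading "within" conventionally.
* **All atoms vs heavy atoms.** The contact test uses all atoms by default;
  `contact_atoms = "heavy"` is available since hydrogen placement is
  model-dependent in some force fields.
* **One contact suffices.** A single qualifying atom pair creates an edge.
  This applies uniformly regardless of molecular topology; a `min_contacts`
  parameter exists for sensitivity analyses but multi-contact grouping has
  no established convention and is not the default.
* **Frames, 5000 equispaced.** Analysis frames are taken at indices
  `floor(i (F-1)/(n-1))`, always including the first and last frame.

### Metrics

The population profile is `P(k) = 100 * #{frames with N_c = k} / #frames`.
Aggregators decay from a mode at small N\_c ("aggregated-exponential"),
non-aggregators from a mode at N\_mol ("dispersed-exponential");
intermediates are bell-shaped. The shape label in reports operationalises
this qualitative language with a heuristic band rule: a mode at k = 1 or
strictly inside the lowest 20% of the k-range is aggregated-exponential,
the mirror case dispersed-exponential, anything else bell. The bounds are
exclusive so that, e.g., a peak at 3 of 11 molecules counts as interior
(bell); ties resolve toward the nearer extreme. It is a label, not a
statistic.

The scalar metric is **fC₅**: the percentage of analysed frames with
N\_c < 5, strictly. A compound is called an **aggregator when fC₅ ≥ 20%**.
The 20% boundary reflects the observed separation in explicit-solvent
screens of drug-like compounds: all experimentally confirmed non-aggregators
fall below 20% while known aggregators appear at 36% and above. There is no
principled derivation of 20%; it is an empirical band and is exposed as a
parameter. Replicate runs are summarised by the mean fC₅ with the sample
(n−1) standard deviation, and classified from the mean.

### Periodic geometry

Boxes are stored as lattice-vector matrices. The truncated octahedron — the
octahedral cell used by solvated screens, here with cell parameter ~180 Å —
is represented as the triclinic cell with a = b = c and all angles
arccos(−1/3) ≈ 109.47°, volume a³√(16/27). Minimum-image displacements use
fractional-coordinate rounding plus a 27-image refinement; rounding alone
can pick the wrong image in skewed cells. The refinement is exact for any
cell at least as regular as the truncated octahedron. The cell-list search
bins atoms in fractional space and requires at least three cells across
every perpendicular box width, guaranteeing it sees every pair within the
cutoff; otherwise it refuses and the exhaustive search must be used
(`method = "auto"` arranges this fallback automatically).

## The synthetic trajectory generator

Since no reference trajectories are distributable, the package ships a
desk-scale generator whose output exercises every analysis path: N
single-bead (or rigid three-bead) molecules in a periodic box under
overdamped Langevin dynamics,

x ← x + (F/γ) Δt + 𝒩(0, √(2 kT Δt/γ)),

with a pairwise interaction split in the Weeks–Chandler–Andersen way: a
fixed repulsive core of 1 kT (Lennard-Jones truncated at 2^{1/6}σ and
shifted) plus an attractive Lennard-Jones tail of well depth ε truncated and
shifted to vanish at 2.5σ. The split makes ε = 0 a purely repulsive
hard-sphere-like fluid and makes ε the exact well depth — ε is the single
dial for aggregation propensity, standing in for the solute hydrophobicity
that drives aggregation in explicit solvent.

Defaults, with units and why:

* `n_molecules = 12`, `box = cubic_box(60)`: the solvated screens use 11–12
  copies; 12 beads of σ = 5 Å in a 60 Å box is a dilute (volume fraction
  ~0.4%) but not kinetically hopeless system.
* `sigma = 5` Å: the effective diameter of a small drug-like molecule
  treated as one bead. Internally the dynamics are in reduced units (σ = 1,
  kT = 1, time unit τ = σ²γ/kT); output coordinates are scaled to Å.
* `dt = 5e-4` τ, `n_steps = 2e5` (100 τ), `save_interval = 100` (2001
  frames): a step small enough that pair forces move a bead a small
  fraction of σ, a span long enough for diffusive encounters (a few τ per
  mean interparticle spacing) and cluster coalescence.
* `epsilon` grid {0, 1, 2, 4} kT spans ideal-gas-like to strong sticking:
  a bonded pair at ε = 4 kT with several neighbours is effectively
  permanent on the run's timescale.
* Placement rejects positions closer than 1.5σ (minimum image), replicating
  the dispersed initial state that a high-temperature pre-equilibration
  phase produces in solvated MD.

Numerical choices:

* **Force capping.** Below r = 0.9σ (pair energy ≳ 18 kT, thermally
  unreachable) the core force is held at its r = 0.9σ value. Explicit Euler
  integration of the raw r⁻¹³ core is unstable once a rare fluctuation
  lands in the stiff region; capping there is the standard Brownian-dynamics
  regularisation and leaves the thermally sampled region untouched.
* **Instability guard.** A centre displacement exceeding σ/2 in one step
  aborts with advice to reduce `dt` rather than silently producing garbage.
* **Reproducibility.** All noise comes from R's RNG, so a seed makes runs
  bitwise reproducible, including through the compiled integrator.
* **Burn-in.** Simulator-driven metrics drop the first 20% of frames
  (`drop_burnin()`), because the artificial dispersed start biases fC₅
  downward. The analysis layer itself never drops frames implicitly —
  burn-in removal is an explicit, opt-in step.

**Bead contact cutoff.** Two σ = 5 Å beads "touch" near the Lennard-Jones
minimum at 1.12σ ≈ 5.6 Å, so the atomistic 3.0 Å centre-to-centre cutoff
can never fire on bead trajectories. `contact_cutoff(cfg)` returns 1.3σ —
just beyond touching, the same notion the 3.0 Å value encodes for atoms —
and simulator-facing analyses use it. `cluster_trajectory()`'s default
stays 3.0 Å for atomistic input.

**What the generator does and does not emulate.** It reproduces the
*phenomenology* the analysis must handle — dispersed, intermediate and
collapsed regimes, dynamic cluster exchange, periodic wrapping — with a
tunable knob where chemistry would be. It has no solvent, electrostatics,
conformational flexibility or chemical specificity, so passing tests on it
validates the clustering and metrics machinery, not any claim about a real
compound's aggregation behaviour.

## Protocol and composition emitters

`default_protocol()` encodes the five-stage recipe (minimisation; NVT
heating 0→500 K over 20 ps, to scatter solutes; NVT cooling 500→300 K over
20 ps; NPT 2 ns at 300 K and 1 atm; 1 µs production at 300 K saving every
20 ps; dynamics at 2 fs with SHAKE, 10 Å cutoff, Langevin γ = 1 ps⁻¹) and
`emit_input_files()` writes it as AMBER-style namelists with sorted keys and
fixed formatting, so emission is byte-stable and `parse_mdin()` round-trips
it. Minimisation cycles and the NPT pressure-coupling scheme are not
dictated by the protocol's source; they are emitted as clearly marked
implementation defaults (the minimisation title line says so explicitly).

`composition()` turns a box and nominal conditions into counts: solute
molarity n/(N_A·V); NaCl pairs `round(c · N_A · V)` (round-half-even, R's
`round`); DMSO count from a 5% v/v fraction via a *named* molar-volume
parameter (default 71.3 cm³/mol at room temperature) rather than a buried
constant. The "~180 Å octahedral box" is interpreted as the
truncated-octahedron cell parameter; a cubic interpretation is available by
constructing the box accordingly.

## Descriptor baseline

`threshold_classify()` implements single-descriptor rules such as
logD > 3 — strict at the boundary, per the rule's wording, with an inclusive
variant by flag. logD (the ionisation-corrected distribution coefficient)
outperforms logP here precisely because charged species have lower
*effective* hydrophobicity. The shipped table
`inst/extdata/compounds_synthetic.csv` is **synthetic**: experimental labels
and the handful of descriptor values quoted in published text are embedded
(see the file's comment header), everything else is invented but arranged to
reproduce the qualitative outcome that the logD rule misclassifies exactly
three of 32 compounds. `success_rate()` reports percent to one decimal with
the offending compound ids; `compare_methods()` tabulates per-compound
agreement across MD calls and descriptor screens.

## Problem sizes used in the checks

The shipped verification runs use: 200 random frames (5–50 molecules, up to
40 atoms each, cubic and truncated-octahedron cells, cutoffs 2–6 Å) for the
cell-list vs brute-force equivalence; 500 random point pairs for
minimum-image geometry; and the ε grid {0, 1, 2, 4} kT × 3 seeds ×
2×10⁵ steps for the simulator's monotone-recovery property. These sizes
give stable statistics for every property tested while keeping a full run
in the tens of seconds on one CPU.

## Known limitations

* The fC₅ threshold (k = 5, 20% decision boundary) is calibrated to
  11–12-copy systems; other copy numbers need rescaled conventions.
* Single-linkage clustering with one qualifying contact is deliberately
  permissive; at cutoffs beyond ~6 Å it merges non-interacting molecules.
* The simulator is a surrogate, not a solvent model (see above); its
  trimers rotate with a simplified isotropic rotational friction.
* The trajectory readers cover extended XYZ (+ molecule-map sidecar),
  multi-MODEL PDB and DCD-with-PDB-topology; AMBER NetCDF is out of scope,
  as is any trajectory alignment (the contact test needs none).
* `profile_shape()` is a labelling heuristic; borderline profiles near the
  band edges should be inspected, not trusted to the label.
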