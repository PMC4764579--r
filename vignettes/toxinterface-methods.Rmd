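---
title: "Methods: contact statistics, map scoring, ensemble geometry and partitioning thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact statistics, map scoring, ensemble geometry and partitioning thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxinterface)
```

This vignette documents the models behind `toxinterface`, the
assumptions they make, the defaults and why they were chosen, and what
the synthetic-data generators do and do not emulate.

## The contact statistic Np

For two disjoint heavy-atom groups A and B, the statistic counted by
`np_pairs()` is the non-normalised inter-group pair-distance
distribution integrated over the first interaction shell, taken to be
6 Å — which is simply the number of atom pairs (a ∈ A, b ∈ B) with
d(a, b) ≤ 6 Å. Averaged over trajectory frames or ensemble models it
measures the persistence of an interaction, and it scales with group
size by design: larger interfaces interact more.

Conventions, fixed in one place and inherited by every application:

* **Inclusive cutoff.** The shell integral is closed at the cutoff, so
  a pair at exactly 6.000 Å counts.
* **Hydrogens are excluded** from counting (they are parsed and
  retained in the data model; the filter lives in the contacts module
  only).
* **Side chain** means heavy atoms excluding the backbone set
  {N, CA, C, O}; CB is side chain. This is the standard PDB convention;
  where an analysis is flagged `sidechain_only` the filter is applied
  to both groups symmetrically.
* **Frames are weighted equally** in all time averages.
* **No periodic-boundary handling.** Inputs are assumed whole and
  unwrapped; wrapped trajectories must be unwrapped upstream.

The production path bins atoms into cubic cells of edge `cutoff` and
examines only the 27 neighbouring cells, which is exact (not an
approximation): the test suite asserts equality with an O(n²)
double-loop oracle on randomised fixtures.

## Density-map scoring

`synthesize_map()` renders a structure as a sum of isotropic Gaussians
of amplitude m_a (atomic mass) and width σ, so the peak value over an
isolated atom equals its mass and the grid sum of a well-padded map
equals Σ m_a (2πσ²)^{3/2}/voxel³ — both used as analytic anchors in the
tests. Maps are held in canonical (x, y, z) axis order; the MRC reader
normalises any MAPC/MAPR/MAPS permutation at read time, so downstream
code never sees permuted grids. Only orthogonal cells and mode-2
(float32, little-endian) maps are supported.

`atom_confidence()` implements the per-atom confidence score
s_a = −m_a·ρ(x_a, y_a, z_a), with ρ interpolated trilinearly on the map
**normalised to unit maximum**. "Normalised density signal" admits more
than one reading; unit-maximum scaling keeps ρ ≤ 1 and scores comparable
across maps, and is the default (`normalize = "none"` exposes raw
values; z-scoring was considered and rejected as it makes the sign of ρ
depend on the mean level). Under the negative sign convention the
*top* fraction (default 0.20) means the *most negative* scores — the
atoms sitting in the densest map regions. Ties are broken by lower
serial so the selection is reproducible under permutation. Atoms
outside the map box get ρ = 0 with a warning, never an error, because
refinement intermediates can poke out of the box.

`rank_poses()` orders candidate placements by map correlation first,
then fewer NOE violations, then lower violation RMSD, then input order.
The two criteria (fit to density, restraint satisfaction) are the ones
used to discriminate mirror-image lobe assignments; the composite
ordering is this package's own deterministic combiner, chosen because a
total, reproducible order is needed and correlation is the better
separated of the two criteria on synthetic fixtures.

The violation RMSD is computed over violated restraints only,
√(mean (d − u)²), and is 0 exactly when nothing is violated. Selectors
that do not resolve to exactly one atom are excluded from the
denominator and reported separately rather than silently dropped.

## Ensemble geometry

* **Superposition** is the SVD Kabsch solution with the determinant
  correction, so reflections are never returned; degenerate (collinear)
  inputs are an error.
* **RMSD to the mean** iterates superpose-all-on-mean / recompute-mean
  until the mean shifts by < 1e-6 Å (cap 100 iterations), then averages
  each model's RMSD to the converged mean. The phrase "deviation to the
  mean" is ambiguous between this and the mean of pairwise RMSDs;
  `method = "pairwise"` exposes the alternative.
* **Daura clustering** greedily picks the model with the most
  neighbours within the cutoff (lowest index on ties), forms a cluster
  from it plus its neighbours, removes them and repeats. The
  representative model is the centre of the largest cluster. The
  pairwise-RMSD path is validated against a hand-traced fixture through
  the same matrix entry point.
* **SASA** is Shrake–Rupley with a deterministic Fibonacci lattice
  (default 960 points), so areas are bit-reproducible — no RNG is
  involved. Probe radius defaults to 1.4 Å (water). The van der Waals
  radii are a fixed Bondi-like table (C 1.70, N 1.55, O 1.52, S 1.80,
  P 1.80 Å); hydrogens are ignored, and an element outside the table is
  an error rather than a guessed radius. Quadrature accuracy is ~1 % on
  a lone sphere and ~2 % on two-sphere cap geometries (asserted in the
  tests); doubling the lattice changes a lone-sphere area by < 0.5 %.
* **Buried interface area** uses the per-complex convention
  (SASA_A + SASA_B − SASA_AB)/2, and per-residue ΔSASA is
  SASA_free − SASA_bound; summed over both partners the ΔSASA equals
  twice the buried area, an identity the tests check to 3 % (the
  quadrature tolerance). Published interface areas computed with other
  radii/probe conventions should be compared only loosely; the radii
  and probe behind reported tryptophan SASA values are typically
  unstated, so agreement within the reported spread is the most that
  can be expected.
* **Residue classes** follow the usual surface-colouring scheme;
  histidine is counted basic.

## Partitioning and dose-response thermodynamics

The titration model is
F/F₀(L) = 1 + (F/F₀ᵐᵃˣ − 1)·Kₓ[L]/([W] + Kₓ[L]) with [W] = 55.3 M and
[L] = 0.6 × total lipid — only the outer leaflet is accessible to a
peptide added from outside, and the 60 % accessibility is applied
*before* fitting. `fit_partition()` runs Levenberg–Marquardt over
(Kₓ, F/F₀ᵐᵃˣ) on all replicate points, unweighted (replicate scatter is
roughly proportional to signal and the points are few; a weighting flag
would be the natural extension), started from Kₓ = [W]/median([L]) and
the largest observed F/F₀, bounded to Kₓ ∈ [1, 10¹⁰], F/F₀ᵐᵃˣ ∈ [1, 20].
If the predicted bound fraction never reaches 0.3 the fit is flagged
low-confidence: Kₓ and the plateau are then nearly collinear, the
classic failure mode of non-saturating titrations.

ΔG° = −RT ln Kₓ with R = 1.987 × 10⁻³ kcal mol⁻¹ K⁻¹. The default
temperature is **293 K** (room-temperature fluorescence); this choice
reproduces the package's bundled reference free energies from their
partition coefficients to one decimal, which was verified over
candidate temperatures 288–300 K before fixing the default. It is
overridable per call.

The Hill model is I = I_min + (I_max − I_min)/(1 + (K_D/[Tx])^s), the
form that increases with concentration and gives the midpoint
(I_min + I_max)/2 at [Tx] = K_D. `fit_hill()` fits all four parameters
by Levenberg–Marquardt; when the observed responses do not span the
transition the fitted K_D is flagged as a lower bound (and standard
errors may be NA when the plateau is unconstrained), mirroring how
weakly-activating constructs are reported. Bivalency analysis is pure
arithmetic: theoretical ΔG° of a construct is the sum of its lobes'
monovalent ΔG°, and the penalty is measured minus theoretical, positive
when tethered lobes partition more weakly than the additive expectation.

The bundled reference table (`reference_partitioning()`) records one
partition coefficient (K2K2) whose order of magnitude is reported
inconsistently at source; the CSV keeps the value consistent with its
own tabulated free energy at 293 K and documents the discrepancy in a
comment.

## What the synthetic data emulate — and what they do not

* `build_toy_complex()` plants contacts by construction: planted
  residue pairs have a heavy-atom pair within 4.5 Å, all other
  inter-chain pairs are beyond 8 Å, so at the 6 Å cutoff recall is 1
  and false positives are 0 *by geometry*. Residues are compact
  4-heavy-atom pseudo-residues; there is no excluded-volume realism, no
  rotamers and no chain connectivity, so passing tests demonstrate the
  counting machinery, not biological contact prediction.
* `build_membrane_slab()` labels head (HEA) and tail (TAI) atoms on a
  planar two-leaflet grid. It is a topology/label fixture; it has no
  force-field geometry and does not emulate lipid packing or dynamics.
* `simulate_titration()` uses multiplicative Gaussian noise
  (fluorescence errors scale with intensity) and
  `simulate_dose_response()` additive Gaussian noise (patch-clamp noise
  is closer to constant in current units). Neither noise magnitude is a
  measured quantity; the defaults (2 % multiplicative; for currents the
  caller supplies the sd, conventionally 2 % of the response range) are
  package conventions and fully configurable. Dose-response points can
  carry replicates, reflecting that experimental points are means over
  several cells.
* `perturb_ensemble()` displaces heavy atoms by isotropic Gaussians and
  rides hydrogens rigidly on their nearest same-residue heavy atom; it
  emulates ensemble spread, not conformational sampling along real
  modes.

All generators are pure functions of their arguments and a seed
(`.Random.seed` is saved and restored), so identical calls are
bit-identical.

## Problem sizes and determinism

The test suite runs at desk scale: toy complexes of 2 × 8–10
pseudo-residues, clouds of 30–50 atoms, maps up to ~40³ voxels,
ensembles of 5–20 models, 50-seed recovery sweeps for the titration and
dose-response fits, and 10–20-seed sweeps for pose ranking and the
cell-list/brute-force equivalence. These sizes were chosen as the
smallest at which each property is non-trivially exercised. Every
stochastic test fixes its seed; the acceptance script takes the seed on
the command line and derives all randomness from it.

## Known limitations

* PDB parsing is fixed-width only: no mmCIF, no hybrid-36 numbering,
  no insertion codes, no altloc handling (the altloc column is ignored),
  no symmetry expansion.
* The element table (and hence mass/radius lookup) covers H, C, N, O,
  S, P — the chemistry of the structures this package targets. Anything
  else errors loudly by design.
* The restraint-table format is a simplified whitespace dialect, a
  stand-in for program-specific restraint files (e.g. Xplor `.tbl`),
  which are not parsed.
* Map correlation assumes a shared grid; there is no resampling, and no
  attempt is made to reproduce correlation coefficients computed by
  external refinement packages over unknown masks.
* Contact statistics assume unwrapped coordinates; there is no
  minimum-image convention.
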