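# toxinterface

Quantitative analytics for structural studies of peptide toxins that act
on membrane ion channels from within the lipid bilayer — the bivalent
tarantula toxin / TRPV1-style problem, where a disulfide-knotted toxin
simultaneously touches the channel's outer pore and the surrounding
membrane. The package is for structural biologists and biophysicists who
have coordinate ensembles (NMR or refined cryo-EM models), density maps,
NOE restraint tables, and wet-lab titration or electrophysiology tables,
and want the bespoke statistics these studies report computed
reproducibly and testably.

## What it computes

**Contact statistics.** The contacting-atom-pair count between two atom
groups A and B,

    Np = ∫₀⁶ 4πr² g(r) dr ,

where g(r) is the non-normalised distribution of inter-group heavy-atom
distances — i.e. the number of heavy-atom pairs within a 6 Å first
interaction shell, averaged over frames. `np_pairs()` is the primitive
(cell-list accelerated, inclusive cutoff, hydrogens excluded);
`residue_contact_matrix()`, `lipid_contact_profile()`,
`cluster_compactness()` and `neighbor_residue_count()` are its
applications to toxin–channel maps, membrane head/tail fingerprints,
hydrophobic-cluster compactness and interface footprints.

**Density-map scoring.** Voxel-wise map–model Pearson correlation
(`map_model_correlation()`), the per-atom confidence score
s_a = −m_a·ρ(x_a, y_a, z_a) on the unit-max-normalised density with
top-20 % selection (`atom_confidence()`), NOE violation statistics
(`noe_violations()`), and composite pose ranking that discriminates
mirror-image lobe placements (`rank_poses()`).

**Ensemble geometry.** Kabsch superposition, RMSD to the iterated mean
structure, Daura neighbour-count clustering with representative
selection, Shrake–Rupley SASA on a deterministic Fibonacci lattice,
buried interface area (SASA_A + SASA_B − SASA_AB)/2, per-residue ΔSASA
between bound and free states, and residue surface classification.

**Partitioning and dose-response thermodynamics.** The mole-fraction
partition model for tryptophan-fluorescence titrations,

    F/F₀(L) = 1 + (F/F₀ᵐᵃˣ − 1) · Kₓ[L] / ([W] + Kₓ[L]) ,

with [L] the accessible (outer-leaflet, 60 %) lipid and [W] = 55.3 M;
nonlinear fits for Kₓ and F/F₀ᵐᵃˣ (`fit_partition()`); ΔG° = −RT ln Kₓ
(`delta_g()`, T = 293 K default); free-energy additivity analysis of
bivalent constructs (`bivalency_report()`); the Hill equation
I = I_min + (I_max − I_min)/(1 + (K_D/[Tx])^s) and its fit
(`fit_hill()`); and the fractional-dissociation ratio.

A synthetic-data module (`build_toy_complex()`, `build_membrane_slab()`,
`synthesize_map()`, `simulate_titration()`, `simulate_dose_response()`,
`perturb_ensemble()`) generates every input with planted ground truth,
so the whole pipeline is testable offline.

## Worked example

```r
library(toxinterface)

# Free-energy additivity of bivalent toxins, from the bundled
# reference partition coefficients
ref <- reference_partitioning()
dg  <- setNames(ref$dg_printed, ref$construct)
bivalency_report(dg[c("K1", "K2")], dg[c("DkTx", "K1K1", "K2K2")],
                 list(DkTx = c("K1", "K2"), K1K1 = c("K1", "K1"),
                      K2K2 = c("K2", "K2")))
#>   construct measured theoretical penalty
#> 1      DkTx     -8.5       -13.3     4.8
#> 2      K1K1     -8.7       -15.0     6.3
#> 3      K2K2     -6.6       -11.6     5.0
```

Each bivalent construct partitions 4.8–6.3 kcal/mol more weakly than the
sum of its lobes' monovalent free energies — the bivalency penalty.

```r
# Contact recovery on a toy complex with three planted contacts
tc <- build_toy_complex(10, c("A", "B"),
        data.frame(chain_a = "A", res_a = c(2, 5, 9),
                   chain_b = "B", res_b = c(3, 6, 1)), seed = 7)
cm <- residue_contact_matrix(tc$structure, list(chain = "A"),
                             list(chain = "B"))
round(cm$row_totals[cm$row_totals > 0], 2)
#> A:2:GLY A:5:GLY A:9:GLY
#>      16      16      16

# Fit a simulated titration back (multiplicative 2 % noise, 4 replicates)
fit_partition(simulate_titration(k_x = 2.3e6, f_max = 2.65,
                                 replicates = 4, seed = 1))
#> <partition_fit> Kx = 2.63e+06 +/- 3.5e+05, F/F0max = 2.64 +/- 0.014,
#>   dG = -8.61 kcal/mol (T = 293 K)
```

The three planted residue pairs are the only nonzero contact rows (16
heavy-atom pairs each), and the fitted Kₓ recovers the generating
2.3 × 10⁶ within its standard error.

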