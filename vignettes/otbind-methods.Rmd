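---
title: "Methods: trajectory analysis of organotin–aromatase binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of organotin-aromatase binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otbind)
```

# Scope and model

`otbind` analyses protein–ligand molecular-dynamics trajectories the way
an end-state binding study of an organotin–aromatase complex is analysed:
superpose and measure RMSD, cluster frames, detect hydrogen bonds and
π-interactions, trace water-mediated bridges, compute radial distribution
functions, and assemble an MM/PBSA-style free-energy ledger with an
interaction-entropy term. The package does not run dynamics, dock
ligands, or solve the Poisson–Boltzmann equation; it consumes an existing
topology and trajectory (or generates synthetic ones with known ground
truth) and produces the derived observables.

Internally everything is in Angstrom, picoseconds, kJ/mol and elementary
charges. GRO input (nm) is converted on read. Boxes are orthorhombic
only; triclinic input is an error. Residue numbering follows the input
file verbatim, because binding-site residues are conventionally cited by
crystal numbering (TRP-224, LEU-372, MET-374, ...).

# Geometry

**Superposition.** `kabsch_align()` is the SVD form of the Kabsch
algorithm with the determinant sign correction, so the returned rotation
is always proper (a reflected input cannot sneak a chirality flip into an
RMSD). At least three non-collinear fit atoms are required; degenerate
fits are an error rather than a silent near-singular solve.

**RMSD statistics.** `rmsd_series()` aligns each frame to a reference on
a *fit* selection (typically the protein backbone or heavy atoms) and
measures RMSD on a possibly different *measure* selection (typically the
ligand), matching the usual practice of removing global tumbling before
asking how much the ligand moves. `series_rmse()` reports the
fluctuation of such a series as its population standard deviation about
the series mean. Whether such a fluctuation statistic uses the population
or the sample normalisation is immaterial at trajectory lengths
(n > 10^3, relative difference < 0.05%); the population form was chosen
and an `about =` argument allows spread about a fixed reference instead.

**Rings.** A ring's normal is the smallest principal axis of its member
atoms (best-fit plane), not a cross product of two bonds: porphyrin-sized
rings pucker, and the plane fit degrades gracefully (the residual is
reported as `planarity_rms`). Normals are sign-normalised to the +z
hemisphere, and every angle between planes is folded into [0°, 90°], the
acute-angle convention for interplanar dihedrals. For a ring pair the
descriptor is (R_cen, d, θ): centroid distance, perpendicular distance
from ring A's centroid to ring B's plane, and the acute interplanar
angle. θ and R_cen are symmetric under ring exchange; d is not (it is a
distance *to ring B's plane*), which is documented and tested rather than
averaged away.

# π–π classification

Contacts are categorised from the descriptor: `NONE` beyond
R_cen > 6.0 Å; `T_SHAPED` when θ ≥ 60°; `STACKED` when θ ≤ 30° and
d ≤ 5.0 Å; otherwise `INTERMEDIATE`. The thresholds bracket the
benchmark geometries of organotin binding — an edge-to-face phenyl–heme
contact at θ ≈ 85°, R_cen ≈ 4.7 Å, and an offset-stacked contact at
θ ≈ 25°, d ≈ 4.2 Å — with generous margins, and every threshold is a
function argument. The four categories partition descriptor space:
exactly one label per descriptor, by construction and by property test.

# Hydrogen bonds, π acceptors, bridges

A hydrogen bond requires acceptor⋯H distance strictly below 2.5 Å *and*
donor–H⋯acceptor angle strictly above 120°, with minimum-image distances
under PBC. Acceptors default to O and N heavy atoms. The distance
criterion is on the H⋯X distance (not donor–acceptor), and the angle is
at the hydrogen — the standard geometric convention. Donor hydrogens come
from the topology (`infer_hydrogens()` attaches each H to its nearest
heavy atom within 1.25 Å from a reference frame).

X–H⋯π bonds treat a ring as the acceptor: the H must lie within 3.0 Å of
the ring centroid and within a 30° cone about the ring normal. The
working cutoff was set slightly above the quantum-chemical equilibrium
H⋯π distance of ~2.7 Å so that thermal fluctuation around a genuine π
hydrogen bond is still detected; both numbers are configurable because
they are detection thresholds, not observables.

`bond_forming_probability()` is the fraction of frames in which at least
one qualifying event joins the named donor and acceptor sites. Because a
reported "average bond distance" can be conditioned either on bonded
frames or on all frames, both statistics are returned
(`mean_distance` over qualifying frames, `mean_distance_all` over all
frames using the closest hydrogen).

**Water bridges.** `find_water_bridges()` builds the frame's
hydrogen-bond graph over ligand sites, waters and protein sites
(collapsing water atoms onto their residue), adds ring nodes as π
acceptors when rings are among the sites, and enumerates all simple
paths ligand → 1..2 waters → protein. Water identity is tracked by
residue id; `bridge_statistics()` reports pattern occupancy (fraction of
frames with ≥ 1 matching bridge) and counts a water *exchange* whenever
the pattern persists across consecutive frames while the set of mediating
water ids changes — the signature of waters swapping in and out of a
persistent bridge.

# Clustering

Frames are clustered by single linkage at a distance cutoff on the
all-pairs Kabsch RMSD matrix: two frames share a cluster iff connected by
a path of pairwise distances strictly below the cutoff, i.e. connected
components of the thresholded graph (computed with igraph; verified
against a hand-written BFS in the tests). The strict `<` boundary is
asserted explicitly. Cluster ids are ordered by decreasing population
with ties broken by lowest member frame; representatives are medoids
(minimum summed RMSD to the rest of the cluster, lowest index on ties).
The 2.0 Å default cutoff is the conventional choice for conformational
clustering of a bound ligand.

# Radial distribution functions

g(r) uses the standard bulk-density normalisation
`hist(r) / (4πr²·dr · ρ_target · N_ref · N_frames)` with the
*instantaneous* box volume per frame, so NPT trajectories normalise
correctly. Reference sites may be atoms or ring centroids; centroids are
recomputed every frame because rings move. Defaults dr = 0.05 Å,
r_max = 12 Å resolve first-shell peaks that differ by 0.2 Å (the
H⋯π shells of inequivalent phenyl rings sit at 2.3/2.5/2.7 Å). Below
~1 Å the shell volume is nearly zero and single background counts produce
huge g values; this excluded-volume region is reported as-is, so
`first_peak()` takes a prominence threshold — for a planted-shell fixture
the a-priori peak height n_shell/(4πr²·dr·ρ) is known and ~10% of it is
the recommended prominence. Peak location is the smallest-r local
maximum with at least that topographic prominence (strictly higher ground
terminates the prominence window, so flat-topped peaks are not
discarded).

# Energetics

**Pair sums.** ΔE_vdW and ΔE_Coul are all-pairs sums between the two
selections with Lorentz–Berthelot combining and minimum-image distances,
*without* a cutoff: end-state interaction energies are conventionally
cutoff-free even when the underlying simulation used one. Overlapping
atoms (r < 0.1 Å) abort with an error since a 12-6 term there is
numerically meaningless.

**Interaction entropy.** −TΔS = k_B·T·ln⟨e^{βΔE}⟩ with
ΔE_i = E_i − ⟨E⟩, computed through log-sum-exp so that βΔE up to ~700
cannot overflow. The estimate is non-negative for any real series
(Jensen) and exactly zero for a constant series; for i.i.d. Gaussian
fluctuations of width σ it converges to σ²/(2k_BT). The default
temperature is 298.15 K — the temperature at which such entropy terms are
conventionally quoted — even when the ensemble ran at 310 K; both are
exposed, and the returned object carries a running per-prefix estimate
with a convergence flag (relative spread of the final 20% below 5%).
Note the estimator is slow-converging when βσ is large: at σ = 10 kJ/mol
(βσ ≈ 4) a 10^6-sample series still carries a Monte-Carlo spread of
roughly ±0.5 kJ/mol and a small negative bias, which is why the test
suite checks its central value over several independent series rather
than one draw.

**Solvation.** The nonpolar term is the linear SASA model
γ·ΔSASA − b with γ = 0.0227 kJ/(mol·Å²), b = 3.849 kJ/mol (the common
gmx_mmpbsa convention; both configurable). SASA is Shrake–Rupley with a
deterministic Fibonacci point set (960 points, 1.4 Å probe), so repeated
calls are bit-identical. The polar term is a pairwise generalized-Born
surrogate with the canonical smoothing function
f_GB = sqrt(r² + R_iR_j·exp(−r²/4R_iR_j)) and fixed, user-supplied Born
radii; it reproduces the Born ion closed form exactly and stands in for a
grid Poisson–Boltzmann solver, which is deliberately out of scope. Its
absolute values are therefore *not* comparable to published PB numbers —
only the ledger identities and component bookkeeping are.

**Ledger.** `mmpbsa_totals()` enforces
ΔE_gas = ΔE_vdW + ΔE_Coul, ΔG_sol = ΔΔG_PB + ΔΔG_SA and
ΔG_bind = ΔE_gas + (−TΔS) + ΔG_sol to 10⁻⁹. Per-residue decomposition
sums each residue's pair energies against the ligand and conserves the
total exactly. `ki_to_delta_g()` uses ΔG = RT·ln(K_i/1 M) with
R = 8.314 J/(mol·K) and T = 310 K by default, the convention that
reproduces published experimental conversions from inhibition constants
(e.g. 50 μM → −25.52 kJ/mol); this T differs from the entropy default by
design and both are arguments.

# Synthetic data: what it emulates, and what it does not

Every analysis stage is validated against generators that plant the
quantity the stage must recover:

* `make_hbond_fixture()` / `make_ring_pair()` build exact requested
  geometries (distance/angle; θ/d/offset), so detection thresholds can be
  probed at the boundary (2.49 vs 2.51 Å, 119.9° vs 120.1°).
* `make_bridge_trajectory()` plants a ligand–water–amide bridge with a
  Bernoulli occupancy and scripted identity swaps of the bridging water.
* `make_ideal_gas()` and `make_shell_fixture()` give the flat-g(r) limit
  and a first shell at an exact radius above a ring.
* `make_two_state_trajectory()` jitters around two conformations whose
  Kabsch RMSD gap is planted exactly (bisection on a displacement
  field); within-state jitter of per-coordinate sd s gives typical
  pairwise RMSDs ≈ √6·s, which is how `intra_spread` is calibrated.
* `make_gaussian_energy_series()` is the σ²/(2k_BT) reference for the
  entropy estimator.
* `make_toy_complex()` assembles all of it: a 5-residue pocket (amide
  donor, carbonyl acceptor, an aromatic ring), a tin-centred ligand with
  hydroxyl, phenyl and butyl-like substituents, and 20 waters, with an
  H-bond planted at occupancy 0.5, a water bridge at 0.7, and a T-shaped
  ring contact (θ ~ 85° ± 2°) in every frame. Charges and LJ parameters
  are a self-contained synthetic table (ligand net charge 0); tin is a
  generic heavy atom with user-supplied parameters.

Identical kind + parameters + seed is byte-identical output, so written
fixtures double as I/O round-trip tests. What the fixtures do *not*
emulate: the real CYP19A1 fold, force-field-quality parameters,
correlated solvent structure, or conformational kinetics. A green suite
therefore demonstrates that each algorithm recovers what was planted
under idealised geometry and statistics — not that any biological claim
about aromatase is reproduced at desk scale, which would require the
original ~100 ns explicit-solvent trajectories.

# Pipeline and problem sizes

`run_pipeline()` merges a user config over `default_config()` (every
number above is a config key), validates it (`validate_config()` returns
findings, never throws), applies the frame-range filter first —
inclusive endpoints, so 3–30 ns at 100 ps is
floor((30000−3000)/100)+1 = 271 frames and at 10 ps 2701 frames — and
runs the enabled stages in dependency order. A failing stage is recorded
as failed in the report and independent stages still run. The report
carries a provenance block (config hash, package version, frame count,
seed) sufficient for bit-identical re-execution.

The shipped tests and the acceptance script size their simulations for
interactive turnaround: the ideal-gas RDF uses 1000 atoms × ~120 frames,
the entropy reference 10^6 samples, the toy complex 400 frames, and the
randomized oracle-equivalence suites 50 fixtures of ≤ 50 atoms — large
enough that every tolerance is dominated by the planted statistics, small
enough to run on one CPU in well under a minute per stage.

# Known limitations

* No triclinic boxes, no velocities, no XTC reader (multi-model PDB is
  the interchange format; GRO is single-frame).
* The GB surrogate uses fixed input Born radii — no self-consistent
  radius calculation — so polar solvation is qualitative by design.
* Bridge enumeration stops at two mediating waters.
* The selection grammar covers names, elements, residues, chains and the
  protein/water/ligand classes; it is not a full molecular query
  language.
* π acceptors participate in bridges only at the chain ends (ligand or
  protein site), not as mediating nodes.
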