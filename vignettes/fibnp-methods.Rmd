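---
title: "Models and methods behind fibnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibnp)
```

`fibnp` implements the analysis layer of nanoparticle–amyloid-fibril coupling
studies together with synthetic structure and trajectory generators. This
vignette explains the models, the statistics, the parameters that matter, and
the numerical decisions — including what the synthetic data do *not* capture
about real simulations, and hence what a passing test suite does and does not
demonstrate.

## The coarse fibril model

A cross-β amyloid fibril is a stack of peptides related by an axial rise and
a small rotation (the twist). `build_fibril()` realises an idealized Aβ40-like
fibril:

* Each peptide is a **U-shaped Cα trace**: residues 1–20 form one extended
  strand (3.8 Å Cα spacing), residues 21–40 the return strand 10 Å away, all
  in one plane perpendicular to the fibril axis (+z). Every residue also
  carries one pseudo-side-chain bead (`CB`) offset ±1.8 Å, alternating with
  residue parity, so each face of a strand exposes alternate side chains —
  the cross-β arrangement that puts Glu22/Asp23 and Lys28 on the exposed
  faces.
* Peptide *j*+1 is peptide *j* translated by the rise (default 4.8 Å, the
  canonical cross-β spacing; 29 peptides then span 13.44 nm, i.e. a 13–14 nm
  fibril) and rotated by the **imposed twist** about the axis. The second
  protofilament is the first rotated 180° about the axis and offset
  laterally.
* **Charges** are residue-level: −1 e on the side bead of Asp/Glu, +1 e on
  Lys/Arg, His neutral, everything else 0; optional zwitterionic termini.
  One Aβ40 peptide is then −3 e, matching its formal charge with neutral
  histidines.
* Residues 1–8 can optionally be rebuilt as a **random-walk coil**
  (`include_disordered_stub`), mimicking the disordered N-terminus; the coil
  never touches residues 18/32, so the twist statistic is unaffected.

Because the Cα(18)→Cα(32) vector of the untwisted template is exactly
perpendicular to the axis, a fibril built with imposed twist θ has *every*
consecutive-pair angle exactly θ — the generator is an analytic ground truth
for the estimator, which the tests exploit (recovery to 1e-6° at θ = 0, 3,
6.48 and 12°).

What the model does **not** emulate: the real Aβ40 fold and its side-chain
packing, hydrogen-bond registry, solvent, and correlated thermal motion.
Trajectory "dynamics" are i.i.d. Gaussian coordinate noise (plus optional
rigid drift) around the reference structure. Passing tests therefore
demonstrate the correctness of the estimators and generators, not the
biology of fibril deformation.

## The nanoparticle model

`build_nanoparticle()` follows the standard recipe: a ~2.2 nm icosahedral Au
shell with 90 ligands. Two geometric requirements collide: a fixed nominal
core diameter and *exactly* equal rigid Au–Au bonds (b0 = 2.74 Å). On a
sphere-projected geodesic shell edge lengths necessarily vary, so the package
subdivides each icosahedron face **in its own plane**: every lattice edge of
a subdivided equilateral triangle is exactly a/ν, hence every bonded pair
sits at exactly b0 (the tests assert 1e-6 Å). The subdivision frequency ν is
chosen from the requested diameter and the shell rescaled so bonds are exact;
for the defaults this yields ν = 4, 162 Au atoms, 480 bonds, and a realised
vertex diameter of 20.85 Å — bond exactness is prioritised over the nominal
22 Å. Gold atoms carry exactly zero partial charge.

Ligand attachment sites are a deterministic **spherical Fibonacci lattice**
("homogeneously distributed", made reproducible rather than random); for
`Janus` particles the two ligand types occupy opposite z-hemispheres of the
attachment sites, separated exactly by a plane. Minority species in mixed
shells (e.g. the 10 NQTrp ligands of `PosNQ`) are interleaved proportionally
along the lattice. Ligands are schematic collinear bead chains with correct
lengths, radii and charges: PEG–ammonium (+1 e), PEG–sulfonate (−1 e),
PEG–NQTrp (neutral, with a rigid planar six-bead ring), and the
charge-inverted peptide ligand Cys-Glu-Leu-Val-Phe-Phe-Ala-Lys-Lys (+1 e net)
derived by `invert_charge_sequence()` from the exposed fibril surface motif.
Net shell charges follow: `Pos` +90 e, `PosNQ` +80 e, `NegNQ` −80 e,
`Janus` 0 e. Torsional realism of the ligands is out of scope.

The `Janus` split (45/45) is a package choice — only the particle's overall
neutrality is prescribed — and is exposed as configuration.

## The twist statistic

θ_twist = (1/m) Σ φ<sub>j,j+1</sub> over consecutive inner peptides, with
φ the **unsigned** angle (arc-cosine of the clamped normalized dot product)
between the Cα(32)→Cα(18) vectors of peptides j and j+1. Decisions:

* Angles are unsigned; handedness of the twist is not resolved. The raw 3-D
  angle is used — vectors are *not* projected onto the plane perpendicular
  to the axis.
* The default ordinal window 4..25 keeps 22 inner peptides of a 29-peptide
  protofilament (m = 21 pairs), excluding termini affected by boundary
  artefacts; out-of-range windows error rather than clip.
* The default frame window is the trailing 500 frames; at the default 10 ps
  spacing that is the final 5 ns, pooling 500 × 21 = 10,500 angles. Shorter
  trajectories error rather than rescale.
* Band percentages use [0°, 10°), [10°, 20°), [20°, 180°] with boundary ties
  going upward, so the three printed groups always partition the pool; the
  distribution histogram defaults to 1° bins.

Because the angle is nonnegative, coordinate noise biases θ_twist upward for
small true twists, and the bias grows with the noise amplitude; the property
suite asserts this ordering over σ ∈ {0, 0.1, 0.3} Å at θ = 6.48°. The
statistic is invariant under any global rigid motion of every frame.

## Monte-Carlo SASA and contact areas

`compute_sasa()` samples `sasa_points` (default 500) uniform points on each
atom's probe-expanded sphere (probe 1.4 Å). A point is accessible iff it lies
outside every other target atom's and every occluder atom's probe-expanded
sphere; a configuration flag switches the occluders to bare van der Waals
spheres for sensitivity analysis (the probe-expanded reading is the default,
i.e. standard Shrake–Rupley). Points come from the seeded RNG per atom index
in a fixed local frame, so results are exactly reproducible and exactly
translation invariant (rotation invariance holds to Monte-Carlo error).
Per-atom area is the accessible fraction times 4π(r + probe)²; every result
carries the binomial standard error, and the tests check the estimator
against closed forms (isolated sphere exact; fused-sphere cap formula within
3 Monte-Carlo SE at 500 points and 0.2 % at 10⁶ points) and the scatter
against a χ² band on the binomial prediction.

The **contact area** is SASA(target alone) − SASA(target with context as
occluders), per frame with identical point sets, then frame-averaged. Both
the full fibril and its β-sheet region (residues 12–40; residues 1–11 are
the disordered "random chain" region) serve as standard contexts. By set
inclusion the full-fibril contact area dominates the β-sheet one in every
frame. Areas convert to nm² by exactly ÷100.

The vdW radii feeding the SASA are carried per atom (PQR input or generator
defaults, Bondi-like values for the schematic beads); the radii source is
configuration, not a hard-wired table.

## Nonbonded energies

`pair_energy()` computes, over **inter-group pairs only** (an interaction
energy, not a total energy; no 1–4 exclusions arise):

* Coulomb: 332.0636/ε · Σ q<sub>i</sub>q<sub>j</sub>/r<sub>ij</sub> kcal/mol
  with ε = 78.5 by default (uniform water-like screening). No cutoff is
  applied in analysis mode — the 10 Å truncation belongs to the LJ term —
  but a Coulomb cutoff flag exists for sensitivity analysis, since post-hoc
  energy tools differ on this point.
* Lennard-Jones (12,6): ε<sub>ij</sub>[(r<sub>min,ij</sub>/r)¹² −
  2(r<sub>min,ij</sub>/r)⁶] for r ≤ 10 Å, plain truncation without switching
  (a post-hoc evaluation, not dynamics), with ε<sub>ij</sub> = √(ε<sub>i</sub>ε<sub>j</sub>)
  and r<sub>min,ij</sub> = r<sub>min,i</sub>/2 + r<sub>min,j</sub>/2 from the
  stored half-values.

LJ pair search uses a cell list that is exact with respect to the brute-force
double loop (asserted to 1e-8 kcal/mol on 100 random 200-atom fixtures with
physical ≥2 Å separations). Energies are attributed to the residue of the
second-group atom in each pair, and the per-residue table sums back to the
totals to 1e-6. Missing charges or LJ parameters raise an explicit
"parameters missing" error listing the atoms — never silent zeros.
`coulomb_grid()` evaluates the point-charge potential φ = 14.3996/ε · Σ q/r
in volts (grid points within 0.5 Å of an atom are masked).

**Sign structure.** The package reproduces the qualitative electrostatics of
NP–fibril coupling on synthetic poses: a +90 e shell posed at the acidic
Glu22/Asp23 face couples attractively (Coulomb < 0), the same shell posed
over the exposed Lys column at the fibril tip couples repulsively
(Coulomb > 0). These assertions evaluate the energy against the β-sheet
region (residues 12–40), which is net-neutral per peptide (Lys16/Lys28 vs
Glu22/Asp23), so with 1/r weighting the *proximal* charged side chains
control the sign robustly; the poses use an untwisted fibril so the charged
columns are straight. Only the directions are asserted — magnitudes depend
on trajectory details no synthetic pose can reproduce.

## Pipeline, poses and problem sizes

`run_pipeline()` chains generate → pose → trajectory → analyses, writes every
stage product (structures as PQR, per-frame tables, a JSON report with file
MD5 provenance and a summary table) and is byte-deterministic under the
configured seeds. The nanoparticle pose starts outward of a surface patch
(the acidic face or the tip Lys column) and slides along the outward
direction until its closest atom sits at the configured gap (default 5 Å,
i.e. the conventional "placed 5–10 Å above the fibril" starting geometry) —
without this refinement a spherical shell posed against a flat fibril face
clashes sterically.

Frame bookkeeping: "the trailing 5 ns" always means the final 500 frames at
10 ps spacing. The twist statistic uses every retained frame; the SASA,
energy and contact stages accept a stride (defaults 50, 10 and 10) because a
Monte-Carlo SASA of a full complex per frame is by far the most expensive
stage and its frame-to-frame information content under i.i.d. noise is low.
The test suite exercises the pipeline on reduced problem sizes (8-peptide
fibrils, 6–20 frames, 100-point SASA) and the full 29-peptide, 500-frame
geometry wherever the assertion concerns counts or exact recovery; these
sizes are the package's validation choices and are trivially enlarged in the
configuration.

## Degenerate inputs and tie-breaks

Zero-length twist vectors, empty angle pools, empty selections, overlapping
group selections, r = 0 atom pairs, negative noise, missing Cα atoms,
out-of-range peptide windows and too-short trajectories all raise immediate,
specific errors. Contact counting is inclusive at exactly the cutoff;
band binning sends boundary ties upward; strict PDB writing refuses >99,999
atoms (hybrid-36 numbering is not implemented) rather than emitting corrupt
serials.

## Known limitations

* The fibril and ligands are schematic bead models; no force-field fidelity
  is claimed, and printed energies/areas from any particular MD study are
  not reproduction targets — they depend on trajectories this package does
  not have.
* Trajectory noise is uncorrelated and isotropic; real fibril fluctuations
  are neither.
* The unsigned twist statistic cannot distinguish left- from right-handed
  twist.
* The realised Au-core diameter is quantised by the bond lattice (20.85 Å at
  the defaults vs the 22 Å nominal).
* Coulomb sums are direct (no Ewald/PME) and the dielectric is uniform; the
  potential grid is a point-charge map, not a Poisson–Boltzmann solution.
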