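# fibnp — nanoparticle–amyloid-fibril coupling analysis

`fibnp` is an R toolkit for studying how ligand-coated gold nanoparticles
(NPs) couple to amyloid-beta (Aβ40) fibrils. It is aimed at computational
biophysicists who want the *post-simulation analysis* layer of such studies —
twist-angle statistics, stochastic solvent-accessible surface areas (SASA)
and contact areas, heavy-atom contact counts, and Coulomb/Lennard-Jones
interaction-energy decomposition — together with fully controllable synthetic
inputs, so that every analysis can be validated against known ground truth
without access to any particular MD trajectory.

## What it computes

**Fibril twist statistic.** Each peptide of a cross-β protofilament carries a
vector from the Cα of residue 32 to the Cα of residue 18. For consecutive
peptides *j*, *j*+1 the unsigned angle φ<sub>j,j+1</sub> between their vectors
is the local twist, and the trajectory statistic is

θ_twist = (1/m) Σ<sub>j</sub> φ<sub>j,j+1</sub>,

averaged over the inner peptide ordinals (default 4–25, so 22 peptides and
m = 21 pairs per frame) and over the trailing 500 frames (5 ns at 10 ps per
frame, 10,500 pooled angles). Pooled angles are also binned into
[0°, 10°), [10°, 20°) and [20°, 180°] percentages.

**Stochastic SASA and contact areas.** Shrake–Rupley-style Monte-Carlo SASA:
`n` points (default 500) are sampled on each atom's probe-expanded sphere
(probe 1.4 Å) and checked against all neighbouring probe-expanded spheres;
a binomial standard error accompanies every estimate. The NP–fibril contact
area is SASA(NP alone) − SASA(NP with the fibril as occluders), evaluated
with identical point sets.

**Contacts and energies.** Heavy-atom contact counts within an inclusive 5 Å
cutoff; screened Coulomb energy 332.0636/ε · Σ q<sub>i</sub>q<sub>j</sub>/r<sub>ij</sub>
(ε = 78.5 for water, no cutoff) plus Lennard-Jones (12,6) energy truncated at
10 Å, with per-residue attribution; and a point-charge electrostatic
potential grid in volts.

**Synthetic generators.** An idealized two-protofilament fibril (29 U-shaped
Cα-trace peptides per protofilament, 4.8 Å rise — 13.44 nm long — with a
controllable per-peptide twist and residue-level charges), the five standard
NP recipes (`Pos`, `PosNQ`, `Pep`, `Janus`, `NegNQ`: a ~2.2 nm icosahedral Au
core with exactly-2.74 Å rigid Au–Au bonds and 90 ligands on a deterministic
Fibonacci lattice), and noisy multi-frame trajectories with known ground
truth.

## Worked example

```r
library(fibnp)

fib <- build_fibril(fibril_spec(n_peptides = 29, imposed_twist = 6.48))
np  <- build_nanoparticle(np_recipe("PosNQ"))
print(fib)
#> <structure_model> role=fibril, 4640 atoms, 58 peptides in 2 protofilament(s)
#>   net charge: -174 e
print(np)
#> <structure_model> role=nanoparticle, 572 atoms, 90 ligands
#>   net charge: +80 e

traj <- synthesize_trajectory(fib, n_frames = 500, noise_sigma = 0.25, rng_seed = 42)
rep  <- compute_twist_report(traj)
print(rep)
#> <twist_report> protofilament 1, 500 frames x 21 pairs (10500 angles)
#>   theta_twist = 6.5274 deg
#>   bands: <10: 100.00%  10-20: 0.00%  >=20: 0.00%
```

The fibril carries −3 e per peptide (Asp/Glu vs Lys/Arg at the residue
level), the `PosNQ` shell is 80 cationic + 10 neutral inhibitor ligands
(+80 e), and the twist statistic recovers the imposed 6.48° per-peptide
rotation; 0.25 Å coordinate noise biases the unsigned-angle mean slightly
upward (6.53°), which is the expected behaviour of a nonnegative angle
estimator. With no noise the recovery is exact to 1e-6°.

An end-to-end run (generate → pose → trajectory → all analyses → JSON report
and summary table):

```r
cfg <- run_config(trajectory = list(n_frames = 500))
rep <- run_pipeline(cfg, out_dir = "out")    # writes out/report.json, out/summary.txt
print(rep)
```

A thin command-line wrapper lives at `inst/scripts/fibnp.R`
(`fibnp.R run config.yaml out/`, `fibnp.R build-np np.pqr PosNQ`, ...).

## Documentation

The methods vignette (`vignettes/fibnp-methods.Rmd`) documents the model
geometry, the statistics, all tunable parameters with units and defaults,
the numerical choices, and what the synthetic generators do and do not
emulate about real fibril simulations.
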