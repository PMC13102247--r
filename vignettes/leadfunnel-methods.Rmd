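---
title: "Methods: consensus docking aggregation and stability triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus docking aggregation and stability triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leadfunnel)
```

# Scope and model

`leadfunnel` re-implements, at desk scale, the computational funnel used
to prioritize natural-product inhibitor candidates against a protein
target (the packaged fixtures come from a PD-1 screening campaign over a
phytochemical library).  The funnel has five stages, each of which this
package implements from its mathematical definition rather than by
wrapping the original engines:

1. **Hit filtering** — retain compounds whose docking energy in a chosen
   program column is below a configurable cutoff (kcal/mol).
2. **Consensus ranking** — per-program competition ranks aggregated by
   radar-polygon area.
3. **Reactivity annotation** — conceptual-DFT global descriptors from
   frontier-orbital energies.
4. **Trajectory analytics** — RMSD, RMSF, Rg, SASA, hydrogen-bond
   counts, Cartesian PCA and Boltzmann-inversion free-energy landscapes
   computed from coordinate frames.
5. **Triage** — MM-PBSA bookkeeping, hard stability criteria and a
   weighted 0–10 stability score.

The docking programs, the DFT electronic-structure calculation and the
MD simulation itself are out of scope: the package consumes their
tabular and trajectory outputs, and a seeded synthetic-data module
generates inputs with known ground truth so that every stage is testable
without those engines.

# Consensus by radar-polygon area

Each docking program column is converted to **competition ("min")
ranks**: rank 1 is the best value under the column's orientation, tied
values share the smallest applicable rank, and the next distinct value
skips the tied count.  This tie policy is not a free choice — it is the
only standard policy consistent with the published rank table the
package ships as a fixture (two scores tied at −7.76 kcal/mol both rank
23 and the next value ranks 25; dense ranking would give 24, average
ranking 23.5).

For a compound with ranks $r_1,\dots,r_n$ on $n$ program axes placed at
equal angles, the radar polygon area is

$$A=\tfrac12\sin\!\left(\tfrac{2\pi}{n}\right)\sum_{j=1}^{n}r_j\,r_{j+1},
\qquad r_{n+1}\equiv r_1,$$

the shoelace area of the closed polygon.  Smaller area means the
compound sits closer to the center (ranks near 1) on all axes, so
compounds are ordered by ascending area.  Two properties matter in
practice and are asserted as tests:

* $A$ is strictly increasing in every single rank (each radius has
  positive coefficient $\tfrac12\sin(2\pi/n)(r_{j-1}+r_{j+1})$), so the
  statistic cannot reward a worse rank; and
* $A$ is invariant under cyclic rotation of the axes but **not** under
  arbitrary axis permutations.  The axis order is therefore part of the
  result's provenance.  The default is the input column order; under it
  the packaged fixture reproduces the published top-6 selection with a
  wide margin (cyclic-sum gap of roughly 439 vs 603 between the 6th and
  7th compounds).

Ties on area are broken by mean rank and then by compound id, a
deterministic choice made for reproducibility; the source study states
none.  Mean-rank and rank-sum baselines are provided for comparison
(they produce identical orderings, since one is a positive multiple of
the other).

Both the −6.0 kcal/mol library-screening cutoff and the −7.0 kcal/mol
hit threshold that appear in the source protocol are configuration
values, not constants; "less than" is implemented strictly, with a flag
for inclusive comparison.

# Conceptual-DFT descriptors

From frontier-orbital energies, with $IP=-E_{\mathrm{HOMO}}$ and
$EA=-E_{\mathrm{LUMO}}$ (Koopmans-type approximation):

$$\chi=\frac{IP+EA}{2},\quad \mu=-\chi,\quad \eta=\frac{IP-EA}{2},\quad
\sigma=\frac1\eta,\quad \omega=\frac{\chi^2}{2\eta}.$$

The published fixture table prints electronegativity with a negative
sign and chemical potential positive — the reverse of the standard
convention.  The default `sign_mode = "standard"` follows the textbook
signs; `sign_mode = "published"` reproduces the printed convention
(magnitudes are identical either way).  Units are carried as labeled in
the source table ("eV") without rescaling, although the magnitudes
suggest Hartree; the package reports what it is given rather than
silently "fixing" units.  A degenerate gap leaves softness and
electrophilicity as `Inf` markers instead of dropping the record.

# Trajectory analytics

All analytics operate on a `trajectory` object: an
`n_frames × n_atoms × 3` coordinate array in Ångström plus a topology
sidecar (masses, van der Waals radii, hydrogen-bond roles, hydrogen
parents) read from CSV.  Readers accept multi-model PDB and plain XYZ;
a `scale` argument converts nm input to Å.

* **Superposition** uses the Kabsch SVD construction with the sign
  correction that excludes reflections; the weighted RMSD it minimizes
  is cross-checked in the tests against an independent
  quaternion-eigenvalue oracle to $10^{-9}$.
* **RMSF** superposes frames to the mean structure (fit to the first
  frame, recompute the mean, refit once) before measuring per-atom
  fluctuation.  Rigid-body fitting slightly inflates the apparent
  fluctuation of low-mobility atoms (rotational jitter grows with
  distance from the center of mass) — a property of the estimator that
  the tests account for by validating heterogeneous-amplitude recovery
  without fitting and homogeneous-amplitude recovery with it.
* **SASA** uses the Shrake–Rupley construction with a deterministic
  Fibonacci lattice (default 960 points), so results are
  bit-reproducible; accuracy is verified against the analytic isolated
  sphere and the two-overlapping-spheres cap formula (within 2% at 960
  points).  Totals are reported in nm² by convention, per-atom values
  in Å².
* **Hydrogen bonds** use the common GROMACS geometric criteria —
  donor–acceptor distance ≤ 3.5 Å and H–D⋯A angle ≤ 30° — both
  configurable, with donor and acceptor restricted to two disjoint
  selections (e.g. ligand vs protein).
* **PCA** is mass-unweighted Cartesian covariance over the flattened
  $3N$ coordinates after superposition, with projections reported in nm.
* **FEL**: the (PC1, PC2) occupancy histogram is Boltzmann-inverted,
  $G_b=-k_BT\ln(P_b/P_{\max})$, so the most occupied bin sits at
  $G = 0$ and empty bins are masked.  At the default 300 K,
  $k_BT = 2.494$ kJ/mol.
* **Equilibrium windows** follow the working definition used in the
  source analysis: a parameter is equilibrated when every value after
  100 ns stays within ±10% of the post-100-ns mean; both numbers are
  arguments.

# MM-PBSA bookkeeping and triage

The energy model carries exactly the four printed terms (van der Waals,
electrostatic, polar solvation, SASA) — no configurational-entropy slot,
matching the g_mmpbsa-style output it mirrors.  The total mean is the
exact sum of term means; the total SD combines term SDs in quadrature.
Both rules reproduce every stated total in the packaged fixture within
0.002 kJ/mol, which verifies that the upstream error propagation was
quadrature.

The hard criteria screen uses strict inequalities: RMSD < 3.5 Å,
RMSF < 1.65 Å, binding energy < −60 kJ/mol (all configurable).  The
stability score maps each raw metric across candidates onto [0, 10] by
a min–max linear map (best → 10; all-equal → midpoint 5) and combines
sub-scores with weights 0.25 (RMSD consistency), 0.25 (RMSF), 0.30
(binding energy), 0.20 (H-bond stability).  Two open choices were
resolved as follows and are exposed as arguments:

* "RMSD consistency" defaults to the SD of the RMSD series (the
  *consistency* reading) with the mean selectable;
* H-bond stability is $10\,(1-\mathrm{CV})$ of the bond-count series,
  clipped to [0, 10], rewarding sustained bonding with low variability.

The source study never defines the mapping behind its printed composite
scores, so those exact numbers are not reproduction targets; what is
reproduced is the decision structure — which compound leads the ranking
and which criteria each candidate passes.  When no hydrogen-bond series
statistics are available (the fixtures print none), the H-bond weight
is dropped and the remaining weights renormalized.

# Synthetic data: what it emulates and what it does not

The generators are pure functions of their arguments and a seed.

* `gen_score_table()` draws a latent affinity per compound
  (default N(−6.5, 0.8²) kcal/mol — the spread typical of a
  pre-filtered hit list, cf. the fixture's per-program SDs of roughly
  0.7–1.9), shifts planted binders by a fixed effect (default
  −3 kcal/mol), and adds independent per-program noise scaled so any
  two columns correlate at ρ (default 0.8).  Additive Gaussian noise on
  a shared latent variable is the simplest structure with a tunable
  inter-program correlation; it is a stand-in, not a model of real
  docking error.
* `gen_trajectory()` adds iid Gaussian displacement of per-atom
  amplitude σᵢ to a fixed reference (so E[RMSF] = σᵢ√3 exactly),
  optionally composed with random global rigid motions; real
  trajectories have correlated, anharmonic motions, so passing
  recovery tests shows estimator correctness, not realism.
* `gen_two_state_projections()` mixes two Gaussian basins with stated
  occupancies; the expected basin-depth difference is
  $k_BT\ln(p_1/p_2)$.
* `gen_mmpbsa()` perturbs term means and recomputes stated totals by
  the same additivity/quadrature rules, so generated tables validate
  by construction until corrupted.

# Numerical choices and problem sizes

Tolerances used by the test suite were fixed from analysis of each
estimator, not tuned: descriptor reproduction at 5×10⁻⁴ (the fixture
prints 3–5 decimals), MM-PBSA at 0.002 kJ/mol (half a unit in the last
printed digit), Kabsch-vs-quaternion at 10⁻⁹, Shrake–Rupley at 2% for
960 points, RMSF amplitude recovery at 5% for 5000 frames × 50 atoms,
and FEL basin depth at 0.2 k_BT for 32 bins and 50 000 samples (the sum
of the ≈0.1 k_BT peak-bin discretization bias at bin/σ ≈ 0.63 and the
peak-bin counting noise).  Degenerate inputs are handled explicitly:
single-frame RMSF warns and returns zeros, an all-equal sub-score maps
to the midpoint, a degenerate orbital gap yields `Inf` markers, and a
zero-range FEL axis is widened by ±0.5 before binning.

# Known limitations

* The radar-area statistic depends on axis order (only cyclic
  rotations are neutral); results record the order used.
* The published composite stability scores cannot be reproduced because
  their mapping was never defined; the package's min–max sub-score is a
  documented replacement with the same weights.
* The fixture rank table lists 32 compounds although the source text
  speaks of 31 hits; readers take tables as given and do not reconcile
  counts.
* Binary trajectory formats (XTC/TRR/DCD) are not parsed; convert to
  multi-model PDB or XYZ first.
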