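---
title: "Methods: loop-conformation clustering and interface statistics for TREM2–ApoE trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop-conformation clustering and interface statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trem2flex)
```

## The analysis in one paragraph

TREM2's CDR2 loop switches between closed and open conformations; the R47H
mutation suppresses that flexibility. The package quantifies this from MD
trajectories through one estimator and a chain of derived statistics. The
estimator is the **SD-threshold cluster model**: Loop 1 — the Cα–Cα distance
between residues 46 and 71, measuring how far CDR2 extends from the Ig-like
core — is pooled over all replicate frames of a variant to give a mean *m*
and sample standard deviation *s* (n − 1 denominator), and every frame is
labelled Cluster A (Loop 1 > m + s), B (m − s ≤ Loop 1 ≤ m + s), or C
(Loop 1 < m − s). Everything downstream is conditioned on these labels:
medoid representative structures per cluster, the 4.0 Å CDR-versus-hinge
filter that picks docked models, per-frame interaction energies classified
by the frame's Loop 1 value, two-way ANOVA with Tukey–Kramer comparisons
across cluster × isoform cells, and occupancy-weighted ensemble energies.

## The cluster model and its assumptions

`loop_clusters()` is deliberately minimal: two parameters (*m*, *s*) and a
three-way partition. It assumes (i) Loop 1 is the coordinate that separates
the conformations of interest, and (ii) one SD around the pooled mean is a
meaningful band. Neither assumption is checked by the estimator itself —
on unimodal data the thresholds simply carve out the ~16/68/16 % tails
(`summary()` on a Gaussian series shows exactly that), while on genuinely
two-state data the A and C labels track the open and closed states. Two
consequences of the definition are worth stating explicitly:

* **Pooling.** *m* and *s* are computed across **all replicates of a variant
  jointly**, not per replicate. A single per-variant threshold pair is what
  makes "Cluster A" comparable across replicates and across the docked
  complexes that are later classified against the same thresholds. A
  per-replicate alternative would let each replicate define its own clusters
  and break that comparability.
* **Boundary frames.** Values exactly equal to m ± s are "within the mean ±
  one standard deviation" and therefore Cluster B. With *s* = 0 the band is
  degenerate; every frame is B and a warning is raised rather than an error,
  since constant series do occur in truncated or synthetic inputs.

For well-separated two-state data the A+C occupancy estimates the fraction
of frames spent in either pure state, but the estimate is asymptotic in the
separation: with balanced occupancy the pooled SD slightly exceeds half the
state separation (s² = p(1−p)Δμ² + σ² ≥ Δμ²/4 at p = ½), so each threshold
sits ≈ σ²/Δμ outside its state mean and each state loses a Φ(−σ/Δμ) tail to
Cluster B. At Δμ = 4σ that bias is ≈ 8 percentage points; it falls below one
point only for Δμ ≳ 40σ. The parameter-recovery tests therefore use Δμ =
80σ, where the residual bias (≈ 0.5 points) is well inside the binomial CI
of the occupancy estimate. On real trajectories, where separations of a few
σ are typical, A+C occupancy should be read as a conservative lower bound on
two-state occupancy, not an unbiased estimate.

## Geometry: superposition, RMSD/RMSF, torsions

`kabsch_superpose()` computes the least-squares optimal rigid transform by
SVD of the weighted cross-covariance matrix, with the determinant correction
that excludes reflections; rank-deficient (collinear) point sets are
rejected. RMSD is computed per frame after fitting by default; fitting can
be disabled to expose drift. Two numerical properties are enforced by tests
rather than assumed: fitted RMSD never exceeds unfitted RMSD, and the fitted
minimum agrees with a quaternion-parameterised multistart search to 1e−6 Å.

**RMSF reference.** `rmsf_profile()` measures fluctuation about the supplied
reference structure (the energy-minimised starting structure), i.e.
sqrt(mean_t |x_i(t) − x_i(ref)|²) after per-frame fitting — not about the
trajectory mean, which is the more common convention. The reference-based
definition is the one used throughout this analysis chain; `about = "mean"`
provides the conventional alternative. The two differ by the displacement of
the trajectory mean from the reference, so reference-based RMSF is always ≥
mean-based RMSF.

**Torsions.** φ(i) = C(i−1)–N(i)–CA(i)–C(i) and ψ(i) = N(i)–CA(i)–C(i)–N(i+1),
IUPAC sign convention (right-handed positive), range (−180°, 180°], trans =
180°. Termini and residues missing backbone atoms yield NA with a
per-residue report. The phrase "φ/ψ angles of Cα atoms" that MD tooling
sometimes prints is read as these standard per-residue backbone torsions;
there is no other well-defined reading.

**Ramachandran regions.** No region boundaries are canonical for motif
*counting*, so the package fixes rectangles chosen to contain the canonical
motif angles with ≥ 20° margins while remaining pairwise disjoint:
right-handed helix φ ∈ [−100, −30), ψ ∈ [−80, −5); left-handed helix
φ ∈ (30, 100], ψ ∈ (5, 80]; β φ ∈ [−180, −45), ψ ∈ [90, 180] ∪ [−180, −150).
Everything else is "other". These are configuration, not science: the counts
(`count_ss_residues()`) are only comparable across simulations analysed with
the same rectangles. Glycine, proline and termini are not treated specially;
all residues with defined angles are counted.

## Interface filter and representative selection

`residue_min_distance_map()` aggregates all-atom distances to per-residue
minima; "within 4.0 Å" means minimum **heavy-atom** distance ≤ 4.0 Å
(inclusive), matching the `within` selection semantics of standard
visualisation tools on crystal structures, which mostly lack hydrogens. A
CA-only mode exists for coarse maps; its distances are necessarily ≥ the
heavy-atom ones. The docking filter scores each pose by the fraction of the
26 CDR residues (8 + 12 + 6) with at least one heavy atom within the cutoff
of any hinge residue (aa167–231, the canonical aa167–191 plus extended
aa192–231 span); ranking is a stable descending sort on that fraction with
model-id tie-breaks. Artifact exclusion (visually detected interconnected
loops in the original workflow) is taken as an input flag — the package does
not invent an artifact detector; excluded models stay in the ranking but
cannot be selected.

Representative structures are **medoids**: the member frame minimising the
summed pairwise fitted Cα RMSD to all other members, ties broken to the
earliest frame. This is a deterministic stand-in for cutoff-based trajectory
clustering tools, whose method and cutoff are rarely reported well enough to
reproduce; the medoid needs no cutoff and is exactly testable against an
exhaustive O(n²) search.

## Energy statistics

Energies arrive as per-frame tables (time, energy in kcal/mol) on the
analysis window — by default 450–500 ns sampled every 0.5 ns, an inclusive
grid of 101 frames per complex, hence 1818 records over the 18 complexes and
909 per TREM2 variant. The window is inclusive at both endpoints; a
non-divisible span is an error rather than a silent truncation.
`classify_energy_frames()` joins energies to Loop 1 on exactly matching
times (misalignment is an error listing the offending times) and labels each
record with the variant's thresholds.

The cell counts that SD-threshold clustering produces are unbalanced by
construction, so `two_way_anova()` uses Type II sums of squares
(`car::Anova` behind the package surface); the interaction is dropped and
reported when empty cells make it unestimable, and zero residual variance is
a hard error. `tukey_kramer()` uses the pooled one-way MSE with the
Tukey–Kramer standard error sqrt(MSE/2·(1/n_i + 1/n_j)) and refers
|Δmean|/SE to the studentized-range distribution; it agrees with
`stats::TukeyHSD` to numerical precision and its type-I error on null data
is verified at the nominal 5 % level over 2000 replications in the
acceptance script (500 in the test suite).

The occupancy-weighted ensemble energy Σ(n_c·Ē_c)/Σ(n_c) is algebraically
the record-wise mean over all frames of the complex — the tests assert the
identity at 1e−12 — but the cluster decomposition is what allows the
most-populated (MP) cluster's mean to be compared against static affinity
measurements. MP ties break to the lowest (most favourable) mean energy and
are flagged. Rank concordance with experiments is Spearman correlation
between −energy and 1/K_D; the experimental affinities are user input, since
no specific values are bundled.

## Synthetic data: what it emulates and what it does not

The generators reproduce the *statistical structure* the analysis assumes,
not the physics:

* `generate_two_state_loop_trajectory()` builds a Cα-only toy protein (a
  20-residue rigid core and a 12-residue loop numbered 67–78 to mirror CDR2)
  whose residue 46–71 anchor distance equals a hidden-state mean plus
  N(0, σ²) jitter; the hidden state follows a symmetric two-state Markov
  chain. Loop opening is a rigid translation along a fixed unit vector, so
  the anchor distance equals the target *exactly* and every geometric claim
  is verifiable in closed form. Defaults (μ_closed = 14 Å, μ_open = 22 Å,
  σ = 0.8 Å, switch probability 0.02/frame) give an ~8 Å open–closed
  separation with dwell times of ~50 frames — loop-scale motion of the right
  order for a CDR loop sampled every 0.5 ns.
* `generate_energy_table()` draws per-cluster Gaussian energies with exact
  requested occupancies and pairs each frame with a Loop 1 value constructed
  to map back to its generating cluster, making label recovery a zero-error
  round-trip by construction.
* `generate_complex_pose()` places one pseudo-heavy-atom per residue so that
  exactly k query residues sit within the cutoff and all others at least
  cutoff + 2 Å away; contact fractions are therefore known exactly.
* `generate_phi_psi_set()` jitters canonical motif angles uniformly and
  warns when the jitter could cross a classification boundary.

All generators are pure functions of (parameters, seed) and restore the
global RNG state. What passing tests on these inputs shows is that the
*computations* are correct — distances, fits, thresholds, counts, SS
decompositions. What they cannot show is that real trajectories satisfy the
model's assumptions: real loops have autocorrelated, non-Gaussian jitter,
more than two states, and energies whose cluster structure is far noisier
than the generator's. The bookkeeping and oracle results transfer to real
data; the parameter-recovery results transfer only to the extent the
two-state picture holds.

## Pipeline, configuration and determinism

`run_pipeline()` composes the stages — simulate, loop metrics, cluster fit,
representative selection, pose scoring, energy statistics — from a single
validated configuration (`validate_config()` collects all errors instead of
failing fast and fills defaults: window 450–500 ns at 0.5 ns, cutoff 4.0 Å,
variants WT/R47H, isoforms E2/E3/E4). Configuration files are YAML, the
idiomatic R configuration format. Every random draw derives from the single
config seed (per-complex sub-seeds are fixed arithmetic offsets), so a
config re-run is byte-identical; the test suite asserts this on the written
CSV artifacts. The synthetic energy model in the pipeline couples energy
linearly to the centred Loop 1 value plus variant and isoform shifts, so
cluster, variant and isoform effects all exist and the downstream statistics
have signal to find, while classification still happens through the same
code path real energy tables would use.

Test and acceptance problem sizes are chosen to make the statistical checks
sharp but quick: 10⁵ draws for tail-mass laws (binomial SE ≈ 0.1 points),
100 random instances for the superposition oracle, 500–2000 null
replications for the type-I rate, and the full 18 × 101 design for the
bookkeeping counts.

## Known limitations

* PDB input is the fixed-column subset (ATOM/HETATM/MODEL/ENDMDL/TER/END):
  no mmCIF, no insertion codes (rejected with an error), first altloc only,
  no compressed trajectory formats. The `md_trajectory` contract isolates
  readers from analysis, so other formats can be added without touching the
  statistics.
* Residue numbering is author numbering; cross-numbering is handled only
  through the region scheme's per-chain offsets.
* The secondary-structure counter is dihedral-region-based by design; it is
  not DSSP and ignores hydrogen-bond patterns.
* The medoid criterion is a documented replacement for unreported
  cutoff-based clustering, not a reproduction of any specific tool's output.
* MM/PBSA energies are consumed, never computed; the CSV contract
  (time_ns, energy, grouping columns) is the boundary.
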