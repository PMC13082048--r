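---
title: "Quantifying transcriptional collisions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptional collisions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnapcollide)
```

This package quantifies what happens to a transcribing RNA polymerase
(RNAP) when it collides with an obstacle on DNA — a DNA-bound roadblock
protein or a second, convergently transcribing polymerase. It covers five
measurements around such collisions: the swivel-module rotation angle of an
elongation complex, the displacement of downstream DNA in a
principal-component frame, a steric-clash profile along the DNA axis from
solvent-excluded-surface (SES) overlap volumes, roadblock-efficiency and
complex-stability quantification from gel data, and orientation/length
profiling of paired 5'/3' RNA reads. A synthetic-data module generates
every input with known ground truth, so the full pipeline is testable
without any external data.

## The swivel angle

Bacterial RNAP pauses long-term by "swiveling": a rigid sub-assembly (the
clamp and associated regions — beta residues 1241–1341 plus four
beta-prime segments) rotates relative to the structural core, kinking the
bridge helix and preventing trigger-loop folding. The angle of that
rotation, measured against an actively elongating reference complex,
summarizes how deeply a structure is paused.

`compute_swivel()` implements the measurement in three steps:

1. pair core C-alpha atoms of query and reference by (chain, author residue
   number), dropping unpaired residues symmetrically, and superpose them by
   least squares (`kabsch_superpose()`, SVD with a determinant correction so
   reflections are impossible);
2. with the query moved into the reference core frame, superpose the
   reference swivel-module C-alpha set onto the query's;
3. convert the rotation part of that second transform to axis–angle form.
   Only the rotation defines the angle; the screw-axis anchor and residual
   translation are reported but unused.

Angles are reported in degrees in [0, 180], the axis signed so the angle is
non-negative. Small angles are extracted with `atan2` of the antisymmetric
part rather than `acos` of the trace, which preserves full precision near
0° (a structure compared against itself reports an angle below 1e-9°);
angles near 180° fall back to the dominant eigenvector of the rotation.

Two choices deserve explanation:

* **Core/swivel overlap.** The published residue lists for the structural
  core and the swivel module overlap in beta-prime 412–420. A residue
  cannot meaningfully belong to both the fixed frame and the moving body,
  so the package trims the overlap out of the *core* (its beta-prime
  segment becomes 421–524) and keeps the swivel module exactly as defined,
  since the swivel module is the measured quantity. At ~1300 core pairs the
  nine removed residues shift the superposition negligibly.
* **Missing residues.** Deposited models rarely resolve every residue. The
  package intersects the selections with residues present in both
  structures; it errors below 50% coverage and warns below 80%. The
  thresholds are policy, not science — they exist to make silent
  degradation impossible.

`swivel_series()` applies the measurement across per-frame models (e.g.
fitted frames of a flexibility trajectory) and reports the min–max range.

## DNA displacement in a PCA frame

DNA deformation downstream of the active site couples mechanically to
swiveling. To measure it reproducibly the package builds a fixed reference
frame once from the reference complex: the centers of mass of twelve
downstream nucleotides are subjected to a principal component analysis
(eigendecomposition of their 3×3 population covariance, 1/N normalization —
the choice affects eigenvalues, never axes). Query structures are
core-aligned to the reference and the per-nucleotide center-of-mass
displacement is projected onto PC1 and PC2; the twelve signed projections
are averaged.

The eigenvectors of a covariance matrix have no intrinsic sign, so the
package fixes a deterministic convention: PC1 points downstream (positive
dot product with the vector from the first to the twelfth reference center
of mass); PC3 is oriented towards the body of the polymerase (by default
the centroid of all reference atoms, configurable via `orient_point`); PC2
completes the right-handed triad. This makes signed displacements
comparable across structures and sessions.

Which twelve nucleotides (and which strand) constitute "downstream DNA" is
configuration, not code: the residue identities differ between scaffolds,
so they arrive as a `residue_selection()`. Centers of mass are
mass-weighted over heavy atoms by default, matching the behaviour of
standard molecular viewers; unweighted and hydrogen-inclusive variants are
flags, because the reference implementations of such extractions differ and
the difference is measurable at the 0.01 Å level.

A note on geometry: PC1 of a helical 12-mer is *not* exactly the helix
axis. Twelve base pairs span ~1.05 helical turns, and the incomplete turn
tilts the leading principal axis of the center-of-mass spiral by roughly 9°
at a realistic ~4.5 Å center-of-mass radius. This is a property of the
covariance, not an artifact; the frame is nevertheless perfectly usable
because it is defined once from the reference and shared by all queries.

`coupling_fit()` is the final step: an ordinary least-squares line (plus
Pearson r) of displacement against swivel angle across structures or
trajectory frames, quantifying deformation–swivel coupling.

## Steric scanning by SES overlap volume

To ask "where along the DNA would the polymerase first clash with the
roadblock?", the package walks a rigid structure base-by-base along the
helical axis and scores each position by the SES overlap volume against the
fixed obstacle:

* `step_transform()` derives the helical screw for one (or n) steps by
  superposing the backbone atoms (P, O5', C5', C4', C3', O3') of a window
  of residues onto the window shifted n residues downstream — a
  homopolymer assumption (residue i maps to i+n by position, not by
  sequence). On ideal B-DNA this recovers a 3.4 Å rise and 360/10.5 ≈
  34.29° twist per step.
* `molecular_volume()` computes the SES volume on a voxel grid as a
  morphological closing: atom spheres (Bondi radii, hydrogens excluded by
  default) are dilated by the probe radius (1.4 Å) and the mask is eroded
  by the probe. The erosion uses a sub-voxel blocking rule — a lattice
  point just inside the inflated surface blocks with its residual reach
  `probe + g`, where `g` is its exact signed distance to the inflated-union
  surface — which removes the half-voxel surface bias of naive boolean
  erosion. A single carbon sphere evaluates to within ~2.5% of the closed
  form already at the default 0.6 Å spacing, and within 1.5% at 0.3 Å.
* `overlap_volume()` is `V(A) + V(B) − V(A ∪ B)` with all three masks on
  one shared, lattice-snapped grid, so it is exactly symmetric and exactly
  zero-to-V-bounded. Positive overlap means the two SES envelopes
  interpenetrate.
* `scan_collision()` combines the two: cumulative step transforms place the
  mobile structure at each scanned nucleotide position, and overlaps are
  rescaled so a chosen reference position (default 39 nt, i.e. a position
  at which the bodies are expected to be clash-free) reads zero.

Closing on a grid fills probe-inaccessible crevices but not large interior
cavities; since overlap differences between nearby positions — not absolute
volumes — carry the signal, this is tolerance-tested rather than corrected.

## Roadblock efficiency and complex stability

`compute_erb()` forms the background-subtracted ratio of roadblock band to
scaffold band intensity; `rescale_titration()` pins the ratio at the anchor
salt concentration (50 mM) to E_RB = 1, and `normalize_erb()` rescales
replicate sets so a designated reference condition has mean exactly 1
(mean ± SD is reported; the division happens after aggregation so the
reference mean is exactly 1 in floating point, not 1 ± 1 ulp). All
normalization identities are scale-invariant by construction and are
property-tested on random tables.

Complex-stability time courses are normalized between a no-NTP control
(fully intact) and a proteinase-K control (background) by
`fraction_intact()`, clipping into [0, 1] with a warning — never silently.
`fit_biexponential()` fits `a1·exp(−k1 t) + a2·exp(−k2 t)` with `a1, a2 ≥
0`, `k1 ≥ k2 ≥ 0` by variable projection: for any rate pair the optimal
non-negative amplitudes have a closed form (2×2 normal equations, else the
better single-column fit), so the optimizer works in the two-dimensional
log-rate space from a grid of multi-starts. Degenerate solutions are
canonicalized (near-equal rates merge; a vanished component carries no
rate), so single-exponential data yield `a2 = 0` rather than an arbitrary
split. The half-life is the time at which the *fitted* curve reaches half
its fitted t = 0 value, found by root bracketing — on a bi-exponential
this is not `ln 2 / k` of either component. The 95% CI is a seeded
parametric bootstrap (Gaussian residual noise around the fitted curve,
refit, percentile interval; 1000 draws by default, configurable). Coverage
of the interval is verified by simulation in the test suite (~90–95% at
12 timepoints, σ = 0.03 — parametric bootstrap percentile intervals
undercover slightly at this n, which is expected behaviour, not a defect).

`compare_conditions()` wraps Welch's two-tailed unpaired t-test
(Satterthwaite degrees of freedom, via `stats::t.test`) over all group
pairs with optional Benjamini–Hochberg adjustment (`stats::p.adjust`).
Doubly-constant group pairs, where the Welch statistic is 0/0, are defined
as t = 0, p = 1 when the means coincide.

## Paired-read classification

Paired 5'/3' RNA reads are assigned to the forward or reverse transcription
direction by alignment: each read is locally aligned against both candidate
RNAs (Smith–Waterman with affine gaps, match +2, mismatch −1, gap open −5,
gap extend −0.5) and each orientation is scored by the sum of its two best
alignment scores; the higher sum wins. Three conventions matter:

* **Gap accounting.** The first position of a gap scores the open penalty
  and each further position the extend penalty (a length-L gap costs
  `open + (L−1)·extend`). This matches the convention of the common Python
  pairwise aligner, *not* the convention of `Biostrings::pairwiseAlignment`
  (which charges open+extend for the first position) — the reason the DP is
  implemented in this package (in C++) rather than delegated.
* **Ties.** An exact inter-orientation tie is ambiguous and the read is
  left unmapped, never assigned arbitrarily. Within one alignment, the
  reported reference interval is the optimal one with the smallest start,
  then the shortest extent.
* **Filters.** The 5'–3' end separation must be strictly greater than 15
  nt, and the 5' end must start within the start-site window, read as
  |5' end − TSS| ≤ window/2 with a 10-nt window (the window's asymmetry is
  not specified anywhere authoritative; the symmetric reading is the
  default and the width is configurable). Reads failing any filter are
  reported with the failure labels, not dropped silently.

`length_profiles()` turns mapped reads into per-orientation transcript
lengths and 3'-end histograms, and computes a hairpin-boundary drop
statistic: mean transcript coverage (reads whose 3' end reaches at least a
position) over the 5 nt just inside the boundary divided by the 5 nt just
outside. Ends piling at the boundary give a large ratio; uniform ends give
~1. The statistic is evaluated on forward-orientation reads, whose
coordinates the hairpin region is specified in; pass `boundary=` explicitly
to evaluate another frame.

## The synthetic-data generators

Every generator is a pure function of its seed (bit-reproducible, and the
caller's RNG stream is saved and restored):

* `make_mock_polymerase()` builds CA-only pseudo-structures on smooth
  random space curves covering the default core/swivel residue layout, then
  rotates the swivel selection by a known angle about a known axis. CA-only
  suffices because the swivel measurement touches only C-alpha positions.
  Default noise is zero; the recovery studies use 0.1 Å per-coordinate
  Gaussian noise, the scale of coordinate uncertainty in well-resolved
  cryo-EM models.
* `make_bdna()` produces an idealized backbone-only duplex (rise 3.4 Å,
  twist 360/10.5° per bp) in which residue i+1 is exactly the helical screw
  image of residue i on both strands — the property `step_transform()`
  relies on. No bases, no sequence: stepping and steric anchoring need
  neither.
* `make_collision_scene()` anchors two deterministic lattice blobs on the
  helix axis, so the first-contact position follows from the blob extents
  and the rise.
* `simulate_reads()` samples reads from the two template RNAs with
  TSS-anchored 5' ends, a configurable 3'-end model (uniform, or piled at
  the hairpin boundary with probability 0.8 by default), and seeded
  substitution errors; the truth table scores the classifier without
  consulting generator internals.
* `simulate_decay()` and `simulate_titration()` produce decay curves and
  gel tables that map back through the controls and normalization exactly
  at zero noise.

What the mocks do *not* emulate: real side-chain mass distributions,
model-building errors correlated along the chain, partial occupancy,
sequencing indels (substitutions only), or gel lane-shape artifacts. Tests
passing on synthetic data therefore validate the *mathematics and
conventions* of the pipeline, not robustness to every pathology of real
data; the structure-facing entry points accept real PDB/mmCIF files
precisely so the same code path runs on deposited models.

## Problem sizes and numerical choices

The shipped validation suite uses: 200 seeded mocks (~4,500 pseudo-atoms
each) for swivel recovery; 100 random perturbation fixtures for the
displacement oracle (agreement to 1e-12 Å); single- and two-sphere SES
closed forms at 0.3 Å spacing (3% and 5% tolerances) and a 45-bp collision
scene at 0.7 Å spacing; 200 seeded noisy decay simulations with 199
bootstrap draws each for CI coverage; the exhaustive set of all ~260,000
sequence pairs of length ≤ 8 over a two-letter alphabet against an
independent plain-R DP oracle; and 200 simulated read pairs for
orientation accuracy. These sizes were chosen so each check is decisively
powered while the whole suite stays quick to run on a laptop.

Other numerical policies, collected in one place: occupancy-tied altloc
conformers resolve to the lexicographically smallest code; Kabsch refuses
collinear point sets (second singular value below 1e-9 of the first);
eigenvalue degeneracy in the DNA frame (collinear centers of mass) is an
error, not a warning; grid origins snap to the spacing lattice so masks of
subsets are commensurate; and every reported mean over the twelve
nucleotides equals the arithmetic mean of the reported per-nucleotide
values to 1e-12 by construction.

## Known limitations

* The swivel measurement assumes both structures share author residue
  numbering after chain mapping; it does not do sequence alignment.
* The steric walk holds both bodies and the DNA rigid; real approach
  trajectories deform all three.
* The drop statistic needs a boundary expressed in the read orientation's
  coordinates; for reverse-orientation profiles the caller must supply it.
* Sigmoid fitting of salt-titration curves is display-level in the source
  assays and is deliberately out of scope here.
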