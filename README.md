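# rnapcollide

Quantitative analysis of transcriptional collisions: what happens,
structurally and biochemically, when a transcribing RNA polymerase (RNAP)
runs into a DNA-bound roadblock protein or into another polymerase coming
the other way.

The package is aimed at structural biologists and biochemists who have (a)
atomic models of elongation complexes (their own or deposited PDB/mmCIF
entries, including per-frame models from flexibility analyses), and/or (b)
the standard bench readouts of collision experiments — gel lane
intensities, complex-decay time courses, paired 5'/3' RNA sequencing reads
— and want the quantities that characterize a collision computed with
explicit, tested conventions.

## What it computes

**Swivel angle.** RNAP pauses durably by rotating a rigid "swivel module"
(β 1241–1341 plus four β′ segments) against its structural core. For a
query structure *Q* and reference elongation complex *R*, the package
superposes paired core Cα atoms by least squares (Kabsch, reflections
excluded), then superposes the reference swivel-module Cα set onto the
core-aligned query's; the rotation part of that transform, in axis–angle
form, is the swivel angle θ:

    T_core  = argmin_T || T(Q_core) − R_core ||        (rigid)
    T_swivel= argmin_T || T(R_swivel) − T_core(Q_swivel) ||
    θ       = angle(T_swivel),  θ ∈ [0°, 180°]

An actively elongating complex scores 0°; paused/backtracked complexes
score up to ~4–6°.

**DNA displacement.** A PCA frame (PC1/PC2/PC3, deterministic sign
convention) is built once from the centers of mass of twelve downstream
nucleotides of the reference; core-aligned query displacements of those
nucleotides are projected onto PC1/PC2 and averaged. `coupling_fit()` then
quantifies deformation–swivel coupling as an OLS line with Pearson r.

**Steric scan.** `scan_collision()` walks a structure base-by-base along
the DNA helical axis (screw transform derived from the DNA itself) and
scores each position by the solvent-excluded-surface overlap volume
V(A) + V(B) − V(A∪B) on a shared voxel grid, rescaled to zero at a
reference position — a clash profile along the collision axis.

**Biochemical quantification.** Roadblock efficiency
E_RB = (roadblock − bg)/(scaffold − bg), anchored to 1 at the 50 mM salt
lane and normalized so a reference condition has mean exactly 1 (± SD);
complex stability by constrained bi-exponential fits
a₁e^(−k₁t) + a₂e^(−k₂t) with bootstrap 95% CIs on the half-life; Welch
t-tests with Benjamini–Hochberg correction for condition comparisons.

**Read classification.** Paired 5'/3' reads are assigned an orientation by
summed affine-gap Smith–Waterman scores against the two candidate RNAs
(match 2, mismatch −1, gap open −5, gap extend −0.5; the first gap position
costs the open penalty), with a strict >15 nt end-separation filter and a
±5 nt start-site window, then profiled into transcript lengths, 3'-end
histograms and a hairpin-boundary drop statistic.

**Synthetic data.** Every input above can be generated with known ground
truth: mock two-module polymerases with a prescribed swivel rotation, ideal
B-DNA (rise 3.4 Å, 10.5 bp/turn), collision scenes, paired reads with a
truth table, decay curves and titration tables. Generators are
bit-reproducible per seed.

## Worked example

```r
library(rnapcollide)

# a mock polymerase pair with a known 2.8 deg swivel and 0.1 A noise
mock <- make_mock_polymerase(seed = 42, swivel_angle = 2.8,
                             coordinate_noise = 0.1)
compute_swivel(mock$query, mock$reference)
#> swivel_result: 2.800 deg (core rmsd 0.176 A over 1328 CA;
#>                           swivel rmsd 0.174 A over 880 CA)

# helical stepping on ideal B-DNA recovers the screw parameters
dna <- make_bdna(60)
win <- residue_selection(c("T", "N"), c(10, 10), c(20, 20))
rotation_to_axis_angle(step_transform(dna, win, 1))
#> axis_angle: 34.2857 deg about (0.0000, 0.0000, 1.0000)

# bi-exponential stability fit with a bootstrap CI
tt <- c(0, 5, 10, 20, 40, 70, 110, 160, 230, 320, 450, 600)
d <- simulate_decay(0.45, 0.06, 0.55, 0.004, tt, noise_sd = 0.03, seed = 7)
f <- fraction_intact(d$signal, d$no_ntp_control, d$pk_control)
fit_biexponential(tt, as.numeric(f), n_boot = 500, seed = 8)
#> decay_fit: a1 0.516 (k1 0.05509 /min), a2 0.472 (k2 0.002745 /min)
#>   half-life 36.87 min (95% CI 29.52-47.75)
```

The swivel result reads back the constructed 2.8° rotation to millidegree
accuracy despite the coordinate noise; the step transform reports the
360/10.5 = 34.2857° twist the helix was built with; the decay fit recovers
a half-life whose CI brackets the true value (~42 min for these
parameters) from noisy 12-point data.

To measure a real structure, read it and supply a chain map if its labels
differ from the canonical `A/B = α, C = β, D = β′, E = ω`:

```r
ref <- read_structure("6rh3.cif")
qry <- read_structure("my_collided_complex.pdb")
compute_swivel(qry, ref, query_chain_map = c(A = "A", B = "B", C = "C",
                                             D = "D", E = "E"))
```

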