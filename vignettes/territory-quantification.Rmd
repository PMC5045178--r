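---
title: "Methods: chromosome-territory quantification and expression statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome-territory quantification and expression statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical choices behind
`xterritory`. The package quantifies chromosome-paint FISH phenotypes of the
*C. elegans* X chromosome — how much of the nucleus the territory occupies,
and how radially it sits — and the chromosome-level expression-ratio
statistics used to measure X derepression when dosage compensation or
heterochromatic tethering is disrupted. Because the original measurements
were made on real worm nuclei and sequencing libraries, validation here is
by parameter recovery on synthetic data generated by the package's own
forward models.

## The synthetic microscopy forward model

`generate_nucleus_stack()` renders one two-channel stack, dims `(z, y, x)`:

* **Nucleus.** A filled ellipsoid in the DNA-stain (`dapi`) channel. The
  default geometry — a 48 × 192 × 192 voxel stack at 0.2 × 0.1 × 0.1 µm and
  nuclear semi-axes 3.5 × 6 × 6 µm — matches a large (~10 µm diameter,
  flattened in z) intestinal nucleus at typical widefield sampling. No
  acquisition voxel sizes are recorded for the original data, so these are
  plumbing defaults, not facts about the source experiments.
* **Territory.** `n_territories` (1 for the single male/XO X, 2 for the
  hermaphrodite homologs) connected blobs in the `probe` channel occupying
  exactly the budgeted number of nuclear voxels,
  `round(territory_fraction · |nucleus|)`. Each blob is the set of budgeted
  voxels nearest its seed point under a per-seed random anisotropic metric;
  since the nucleus and the metric balls are convex, each blob is connected
  and the ground-truth volume fraction is exact by construction. Two
  homologs split the budget equally (rebalanced only if a degenerate
  partition at low radial bias would starve one of them) and are seeded at
  least 120° apart.
* **Radial placement.** Seed points sit at normalized elliptical radius
  `radial_bias` (0 = centre, 1 = envelope) along a random direction in the
  equatorial plane, so every territory crosses the true mid-plane and the
  ground-truth zone masses are always defined. The mean territory-centroid
  radius is monotone in `radial_bias` (tested over 20 seeds).
* **Optics and noise.** Both channels are blurred with a separable Gaussian
  (`blur_sigma` µm, converted to voxels per axis; implemented as per-axis
  banded-kernel matrix products, kernels truncated at 4σ and renormalised
  at the edges) and then corrupted with additive Gaussian noise clipped at
  zero. Blur before noise; defaults `blur_sigma = 0.15` µm and
  `noise_sd = 8` on a probe amplitude of 150 over background 10 give a
  mid-contrast image on which Otsu thresholding is comfortable but not
  trivial. Optional bright puncta (`foci_count`) stress the component-size
  filter. No point-spread-function realism, photobleaching or camera noise
  model is attempted.

**Cohorts.** `generate_cohort()` derives per-nucleus seeds from the cohort
seed by a fixed affine rule (`derive_seed()`), jitters nuclear size with a
truncated (±2.5 sd, and clamped to what the stack margin admits) lognormal
scale of all semi-axes (`size_cv`, default 0.10 — FISH preparations show
large nucleus-to-nucleus size variability, which is why volumes are
normalized to the nucleus at all), and jitters the per-nucleus territory
fraction multiplicatively (`fraction_cv`, default 0.15, truncated normal,
mean preserved). The fraction jitter is the model's stand-in for biological
variability: without it, cohort recovery is so precise that a t-test
between two cohorts generated at the same fraction flags sub-0.1-point
seed effects as significant, which no real cohort would show.

**Ground truth.** For every nucleus the generator emits the pre-blur masks,
the exact volume-fraction percent, the mid-plane index, and the analytic
three-zone masses of the territory's mid-plane pixels measured against the
continuous nuclear ellipse cross-section (not a pixelated zone mask), which
avoids discretization bias in the oracle. `calibrate_radial_bias()` inverts
the monotone bias → central-mass relation by bisection with the per-seed
random draws held fixed, so cohorts can be pinned to a chosen ground-truth
central-zone mass (e.g. the wild-type 20%).

## Volume quantification

`measure_volume_fraction()` reproduces the cross-mask procedure: threshold
each channel, count the overlap, divide by the nuclear count.

* **Thresholds.** The original analysis used a user-defined threshold held
  fixed across nuclei; the recorded procedure specifies only the ratio
  computation. The package's default is deterministic Otsu (256-bin
  between-class variance, ties resolved to the mean maximizing bin) on the
  whole dapi channel, and on the *within-nucleus* histogram for the probe
  (outside-nucleus background would otherwise dominate the probe
  histogram). Both thresholds accept manual overrides per cohort, which
  reproduces the fixed-background policy. The mask rule is `>= t`, fixed so
  that exact tests are possible.
* **Post-processing.** Dapi: largest 26-connected component, holes filled
  per z-slice. Probe: all components of at least 27 voxels kept (two
  homolog territories must survive; 27 voxels ≈ a 3×3×3 speck is the
  smallest structure treated as signal). The numerator is the overlap
  `|probe ∧ dapi|`, not the raw probe count.
* **Properties.** The measurement equals a brute-force triple-loop count on
  small stacks; it is monotone in the probe threshold; and it is invariant
  to joint rescaling of intensities and thresholds. Recovery on synthetic
  cohorts is accurate to a few hundredths of a point at the default
  contrast, well inside the 1.5-point acceptance band.

## The three-zone radial assay

`run_zonal_assay()` composes: segmentation → mid-plane selection →
eligibility → ellipse fit → equal-area zones → zone fractions.

* **Mid-plane.** The z-section with the largest probe-mask count within the
  central third of the stack (the original rule says "toward the middle"
  without a window; a fixed central-third window plus max-signal rule is
  deterministic). Ties break toward the window centre, then the lower index.
* **Eligibility.** The original analysis kept "spherical or ellipsoid
  shaped" nuclei by eye. Operationalized on the largest component of the
  mid-plane nuclear mask as axis ratio b/a ≥ 0.5 and solidity ≥ 0.85
  (pixel count over the convex hull of the pixel squares — exact for convex
  shapes, so a filled rectangle scores 1). Both limits are config-exposed;
  cohorts report the percent eligible.
* **Ellipse.** Hand-drawn ovals are replaced by the moments-equivalent
  ellipse of the mid-plane mask (centroid + second central moments with the
  1/12 within-pixel variance; semi-axis = 2·√eigenvalue). Whether the
  original ovals were centred on the centroid is unknowable; the moment fit
  is a reproducible substitute, accurate to ~2% on synthetic ellipses.
* **Zones.** Central = ellipse scaled by √(1/3), intermediate = √(2/3)
  shell, peripheral = outer shell; each pixel assigned by its centre to the
  innermost containing zone. Pixel areas agree within 1% for a ≥ 100 px.
  Fractions are probe-mask pixel counts per zone divided by the three-zone
  total (mask membership, not raw intensity, matching the voxel-counting
  procedure). Both homolog territories are pooled in one mask — whether the
  original analysis pooled them is unstated, but the probe mask does not
  distinguish homologs. Zone geometry requires isotropic xy sampling
  (anisotropic xy raises an error rather than silently distorting areas);
  ellipses clipped by the image border are flagged and excluded by default.

## Genotype statistics

The comparisons use the classic equal-variance Student's t-test (not Welch
— the equal-variance form is the test named in the original figure
captions), two-sided, with stars at 0.05/0.01/0.001 and **no
multiple-testing correction**, deliberately matching the original analyses;
this is stated prominently because raw per-comparison p-values are what the
stars mean here. Under the null the empirical type-I error at α = 0.05 is
0.05 ± 0.01 (10,000 simulated cohort pairs, n = 20).

Male rescue: `100 · males / (0.38 · eggs)` — the him-8 background yields
38% male progeny, so 0.38 · eggs is the expected male count at full rescue.
The chi-square rescue test is a two-cell (male / non-male) goodness-of-fit
with 1 df against expected counts from a reference rescue rate (e.g. the
vector-RNAi background); expected cells below 1 set a warning flag rather
than failing. The two-cell reading of the raw/expected table is a design
choice; the original table structure is not fully specified.

## Expression statistics

`simulate_expression()` draws per-gene baselines log-normally
(log2 mean 3, sd 2 — median ~8 RPKM with a realistic dynamic range), then
multiplies each non-control condition by `2^(class shift + gene noise)`
(`gene_noise_sd` default 0.3) and every replicate by `2^(replicate noise)`
(sd 0.2, 3 replicates per condition). The control condition is the
reference: shift 0, no gene-level noise. Because the gene noise is
symmetric, the class median of the log2 ratios recovers the class shift;
per-gene responses across two treatments are independent by default, so
cross-treatment correlations reflect only the shared control replicates —
real data, with correlated per-gene responses, shows stronger quadrant
concentration and higher r than the generator reproduces. Gene counts per
chromosome (2,900/3,200/2,600/3,300/5,000/2,800 for I–V, X) approximate the
annotated genome; the X length is taken as 17.0 Mb so the left/middle/right
partition (0–4 / 4–15.75 / 15.75–17 Mb, half-open intervals with the final
boundary closed) covers every simulated X gene. These counts are
configurable plumbing, not facts about the source libraries.

`log2_ratio_table()` filters on the grand mean across *all* samples
(> 1 RPKM), then takes `log2(mean condition / mean control)`. The filter
order (filter, then ratio of replicate means) is the symmetric reading of
the recorded procedure, which states the filter but not the averaging
order. Note the filter interacts slightly with the shift: down-shifted
genes near the 1-RPKM boundary are more often removed, biasing the
autosomal median ~0.005 toward zero at the default settings — the same
selection effect is present in any filtered differential analysis, and it
sits well inside the ±0.02 recovery band.

`wilcoxon_rank_sum()` is implemented in the package rather than delegated:
the contract requires exact enumeration *with midranks* for combined
n ≤ 12 (ties included), which `stats::wilcox.test` does not provide (it
abandons the exact path on ties). Above the cutoff it uses the normal
approximation with tie correction and a 0.5 continuity correction, and
agrees with `stats::wilcox.test` to machine precision on that path (and on
the tie-free exact path), which serves as the independent cross-check in
the tests. Completely tied data return p = 1. The one-sided alternative is
fixed as "X greater" — the working hypothesis is X derepression.

## Problem sizes and determinism

Unit tests run on a reduced geometry (24 × 96 × 96 voxels, ~2 µm z semi-axis)
chosen so the whole suite exercises every code path on realistic shapes in
tens of seconds; the acceptance checks and `scripts/acceptance.R` use the
full default geometry with the study's cohort sizes (20 nuclei for volumes,
10 for the three-zone assay, ~20,000 genes). Every random step is seeded:
cohort members and acceptance targets derive sub-seeds deterministically,
identical configs give byte-identical output tables, and identical
`(spec, seed)` pairs give bit-identical stacks.

## Known limitations

* The threshold default (Otsu) is a stand-in for an unrecorded user-defined
  threshold; absolute agreement with the original Slidebook masks cannot be
  established, only the procedure's behaviour on known ground truth.
* The territory model is a compact connected blob; it does not emulate
  lobed or fragmented territories, so eligibility and zone statistics on
  such nuclei are untested against truth.
* The expression generator has independent per-gene responses across
  conditions and no count-based noise model (no length/GC effects, no
  dispersion-mean relation); it validates the ratio/median/rank statistics,
  not differential-expression calling, which is out of scope.
* Zone geometry is a single-plane construction, not a 3D radial-shell
  analysis.
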