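# xterritory

Quantification of chromosome territories in 3D fluorescence microscopy of
*C. elegans* intestinal nuclei, and of chromosome-level gene-expression
changes under disrupted dosage compensation.

In XX hermaphrodites the dosage compensation complex (DCC) binds both X
chromosomes, compacts their territories and keeps them near the nuclear
lamina; disrupting the DCC or the H3K9me/CEC-4/LEM-2 tethering pathway
decondenses the X and moves it toward the nuclear interior, with a small
chromosome-wide derepression of X-linked genes. This package implements the
image quantification and the statistics used to measure those phenotypes,
together with forward-model generators (synthetic two-channel image stacks
and synthetic expression tables) with known ground truth, so every estimator
can be validated by parameter recovery without access to the original
microscopy or sequencing data.

## What it computes

**Territory volume fraction.** Intensity-threshold 3D masks per channel
(Otsu default on a 256-bin histogram, manual override available; mask rule
is `intensity >= t`). The DNA-stain (DAPI) mask is the primary mask (largest
26-connected component, holes filled per slice); the paint-probe mask is the
secondary mask (components >= 27 voxels kept). The statistic is the
cross-mask overlap

&nbsp;&nbsp;&nbsp;&nbsp;V% = 100 · |probe ∧ dapi| / |dapi|,

the percent of nuclear volume occupied by the painted chromosome.

**Three-zone radial assay.** On the mid focal plane (the z-section in the
central third of the stack with the most probe signal), the nuclear
cross-section is fit by its moments-equivalent ellipse and divided into
three concentric zones of equal area — central (ellipse scaled by √(1/3)),
intermediate (√(2/3) shell) and peripheral (outer shell). The reported
profile is the fraction of probe-mask pixels per zone, normalized over the
three zones. Nuclei must be "spherical or ellipsoid shaped": minor/major
axis ratio >= 0.5 and solidity >= 0.85, with the cohort eligibility rate
reported.

**Genotype statistics.** Classic (equal-variance) Student's t-tests of each
genotype against a reference with significance stars (n.s. > 0.05, \* <=
0.05, \*\* <= 0.01, \*\*\* <= 0.001; no multiple-testing correction,
matching the original analyses), male-rescue percent
(100 · males / (0.38 · eggs laid)) and the two-cell chi-square rescue test
(1 df) against an expected rescue rate.

**Expression-ratio statistics.** Per-gene log2 ratios of replicate means
after a 1-RPKM grand-mean filter; per-chromosome medians; one-sided (X
greater) Wilcoxon rank-sum tests of X vs autosomes and X vs each autosome,
two-sided tests of each autosome vs the rest of the genome (exact
enumeration with midranks up to combined n = 12, tie- and
continuity-corrected normal approximation above); X left/middle/right region
comparison (0–4, 4–15.75, 15.75–17 Mb); quadrant analysis at a 0.1 log2
cutoff; per-chromosome Pearson r and regression R².

## Worked example

```r
library(xterritory)

# one synthetic wild-type-like nucleus: two X homolog territories painted
# at 10% of nuclear volume, near the nuclear envelope
spec <- imaging_spec(territory_fraction = 0.10, n_territories = 2L,
                     radial_bias = 0.8)
nuc <- generate_nucleus_stack(spec, seed = 42)
nuc$truth
#> <ground_truth> territory 10.00% of 263664 nucleus voxels; mid-plane z=24;
#>   zones (P/I/C) 0.424/0.480/0.096

measure_volume_fraction(nuc$stack)
#> <nucleus_measurement> n001: 9.97% of 263959 nuclear voxels (overlap 26311)

run_zonal_assay(nuc$stack)
#> <zone_profile> plane 24, P/I/C = 0.424/0.481/0.095
```

The measured 9.97% recovers the generated 10% ground truth to within a few
hundredths of a point, and the recovered zone profile matches the
ground-truth zone masses (0.424/0.480/0.096): with `radial_bias = 0.8` the
territories sit toward the nuclear envelope, leaving under 10% of the
signal in the central zone. The numbered drivers under `analysis/` run the full
study-shaped experiments (genotype panels for volume and radial position,
the rescue panel, and the expression comparisons) and write their tables
under `results/`.

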