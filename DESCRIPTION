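Package: xterritory
Title: Chromosome Territory Volume, Radial Position, and X-Linked
    Expression Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification of chromosome territories in 3D
    fluorescence microscopy of C. elegans intestinal nuclei:
    threshold-based volume fractions (territory voxels over nuclear
    voxels), the three-zone equal-area radial assay on the nuclear
    mid-plane, genotype comparison statistics (Student's t-test with
    significance stars, male-rescue percent, chi-square rescue test),
    and chromosome-level log2 expression-ratio statistics (Wilcoxon
    rank-sum shift tests, X-region comparisons, quadrant and
    correlation analyses). Includes forward-model generators for
    synthetic two-channel nucleus stacks and gene expression tables
    with known ground truth, so every quantification is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    Rcpp,
    tiff,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
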