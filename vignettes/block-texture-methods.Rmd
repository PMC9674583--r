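---
title: "Methods: block-based patch and texture analysis of super-resolution images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-based patch and texture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

The package quantifies how a fluorescence signal — in the motivating
application, hyaluronan stained for STED imaging at 25 nm pixel sampling —
is organised at the nanoscale inside an expert-marked region of a cell (the
lamellipodium or cell periphery). Two families of per-block descriptors are
computed and compared between conditions:

1. **Patch statistics** treat the signal as a set of discrete bright
   clusters: patch count, mean patch area, and two intensity readouts.
2. **Texture statistics** treat it as a spatial field: Haralick energy,
   contrast and homogeneity of gray-level co-occurrence matrices (GLCMs),
   reduced to rotation- and offset-invariant scalars, plus heterogeneity
   defined as `1 - homogeneity`.

## Grid segmentation

Each image is tiled from its top-left corner into constant-size blocks
(default 100 × 100 px, i.e. 2.5 µm at 25 nm pixels). Coordinates are 0-based
`(row, col)` with half-open block bounds, which removes any off-by-one
ambiguity. Every block containing at least one pixel of the markup mask —
partially or wholly overlapped — is analysed. Truncated remainder blocks at
the right and bottom edges are excluded by default because both patch and
texture statistics depend on the block area; a flag retains them. Note the
nominal block edge of 2.5 µm assumes exactly 25 nm pixels; the block size in
*pixels* is the authoritative quantity and the physical pixel size is
carried as metadata only.

Intensities are analysed raw: no normalisation is applied within or across
images, matching how deconvolved STED exports are produced.

## Patch statistics

Each selected block is binarised with Otsu's method computed *per block*: a
256-bin histogram spans the block's own min–max range, and the cut
maximising the between-class variance (computed in bin-index space, which is
what a histogram method thresholds) is chosen, ties broken towards the
lowest cut so the result is deterministic. Pixels strictly greater than the
threshold are foreground. A constant block has no separable classes and
yields zero patches with all patch means undefined; its texture is still
computed (a constant block has a perfectly well-defined GLCM), so block
counts are preserved across features.

Foreground pixels are grouped into **8-connected** components — diagonal
contact joins a patch — labelled in row-major first-encounter order. No
minimum patch size is imposed by default (`min_patch_area_px = 1`), since
single-pixel components are legitimate sub-diffraction detections at this
sampling; the filter is exposed for users who want one.

Two intensity readouts are kept deliberately distinct:

* `mean_fg_intensity` — the mean original intensity over all foreground
  pixels (the binarised block used as a mask);
* `mean_intensity_per_patch` — the unweighted mean over patches of each
  patch's mean intensity.

They answer different questions (pooled signal density vs typical cluster
density) and can rank conditions differently, so both are reported.

## Texture

Intensities are quantised to 64 gray levels over the block min–max by
default. The level count is a convention: 64 keeps the 64² co-occurrence
histogram reasonably occupied in a 10⁴-pixel block while limiting
discretisation artefacts; both the level count and the quantisation range
(per-block or a fixed global range) are configurable. GLCMs are formed at
twelve offsets `[dx, dy]`: distances 1–4 at 0° (`[k,0]`), 45° (`[k,k]`) and
90° (`[0,k]`). No 135° offsets are computed, by fidelity to the twelve-offset
design. GLCMs are symmetric by default (each pair counted in both orders) and
normalised to sum 1.

Per GLCM, with `p(i,j)` the normalised co-occurrence probability:

* energy `= Σ p(i,j)²`
* contrast `= Σ (i−j)² p(i,j)`
* homogeneity `= Σ p(i,j) / (1 + (i−j)²)` (Haralick's inverse difference
  moment; the `1/(1+|i−j|)` variant is a configuration switch)

Each feature's twelve values are arranged as a 4 × 3 distance-by-angle
matrix and reduced to a single scalar by the matrix's **leading singular
value**, scaled by `1/√12`. A non-square matrix has no eigenvalues, so the
"first eigenvalue" reduction is interpreted as the leading singular value —
the standard rotation-invariant reduction in this family of methods.
Singular values are invariant under any permutation of rows or columns, and
the `1/√(rows·cols)` scaling makes a constant matrix a fixed point: a block
whose feature is the same at every offset returns exactly that value.
Heterogeneity is `1 − homogeneity` computed from the invariant homogeneity.

### What "rotation invariant" can and cannot mean here

The testable content of rotation/offset robustness, given the twelve
offsets, is:

* **180° rotations**: every offset maps to its negative; with symmetric
  GLCMs all three invariant features are *exactly* unchanged.
* **90°/270° rotations**: the 0° and 90° offset families swap — a column
  permutation under which the singular values, hence the invariant form of
  the axis-aligned columns, are exactly unchanged. The 45° offsets, however,
  map to the 135° family, which is *not* among the computed offsets, so full
  three-column invariance under 90° rotation is approximate, not exact, for
  anisotropic blocks.

The test suite asserts the two exact statements (relative tolerance 10⁻⁶)
rather than a claim the offset set cannot support.

## Group comparison

All selected blocks of a group are pooled into one sample per feature — the
literal procedure. This treats blocks from the same image as independent,
which understates within-image correlation; per-image aggregation
(`pooling = "image"`) is available for sensitivity analysis, and the block
counts per group are always reported.

Per feature, the package computes:

* **Mann–Whitney U** with the tie convention `U = Σ[x>y] + ½Σ[x=y]`;
  two-sided p exact (full null distribution) when `n·m ≤ 400` with no ties,
  otherwise a normal approximation with tie-corrected variance and
  continuity correction. Two-sided tests throughout.
* **Bootstrap difference of medians**: groups resampled independently with
  replacement (default 10 000 replicates), percentile 95% interval. The
  percentile interval is the simplest method consistent with a plain
  difference-of-medians bootstrap; BCa was considered and left out to keep
  the inferential object elementary.
* **SE of the median** as the standard deviation of bootstrap medians — the
  estimator is otherwise unspecified in common practice and the bootstrap is
  assumption-free — and **notched-box statistics** with notches at
  `median ± 2·SE(median)` and quartiles by linear interpolation (R type 7).

Seven features are compared by default: `patch_count`,
`mean_patch_area_px`, `mean_fg_intensity`, `mean_intensity_per_patch`,
`energy`, `contrast`, `heterogeneity`. Homogeneity is excluded because
`heterogeneity = 1 − homogeneity` produces the identical test; it remains in
the feature table. No multiple-testing correction is applied by default
(the seven features are strongly dependent readouts of one signal);
Bonferroni and Benjamini–Hochberg are available via configuration.

All stochastic steps take explicit seeds and restore the caller's RNG
state, so a full simulate → extract → compare run is byte-reproducible from
one master seed.

# The synthetic generator

`simulate_cell_image()` renders `background + Σ isotropic Gaussian spots`
with σ equal to the cluster radius, at centres drawn from a homogeneous
spatial Poisson process restricted to the ROI, then applies per-pixel
Poisson shot noise. The Gaussian spot is the simplest model of a
sub-diffraction cluster rendered through a deconvolved point-spread
function; homogeneous placement is a neutral null, with condition
differences expressed purely through count, size and intensity — the three
quantities the analysis measures. The ROI is an axis-aligned band along the
top edge covering 30% of the frame (a crude lamellipodium stand-in,
sufficient to exercise block selection) or an arbitrary polygon.

Default presets, chosen once as a plausible regime for this kind of data:

| parameter | control | invasive-like | note |
|---|---|---|---|
| clusters per 100×100-px block | 12 | 24 (×2) | ~12 clusters per 2.5 µm² |
| radius σ (px) | 2 | 3 (×1.5) | 50 nm at 25 nm/px, sub-diffraction |
| radius CV | 0.25 | 0.25 | lognormal |
| peak intensity (photons) | 120 | 84 (×0.7) | lognormal, CV 0.3 |
| background (photons) | 5 | 5 | Poisson noise |
| frame | 1024² px | 1024² px | typical acquisition frame |

The invasive-like preset applies ×2 / ×1.5 / ×0.7 multipliers to density,
radius and peak intensity, mirroring the direction of the reported
phenotype contrast (more clusters, ~50% larger, lower per-cluster
intensity). The magnitudes are conventions — no quantitative ground truth
for real cluster densities exists to calibrate against — so end-to-end tests
assert *directions* and *monotone recovery*, not absolute values.

What the generator does **not** emulate: STED optics and depletion
physics, deconvolution artefacts, spatially varying background, cluster
shape anisotropy, spatial clustering of clusters, and multi-channel
crosstalk. Passing tests therefore demonstrate that the pipeline measures
what it claims on data of known composition, not that real hyaluronan
images satisfy the generator's assumptions.

# Numerical and degenerate-input choices

* Otsu: 256 bins, tie → lowest cut, foreground strictly `> threshold`;
  adding a constant to a block leaves the partition unchanged by
  construction.
* Quantisation: `floor(levels·(v−min)/(max−min))` clipped to `levels−1`;
  constant blocks map to bin 0.
* A GLCM offset larger than the block is an error naming the offset; blocks
  must be at least 5 × 5 for the default offsets (grid blocks are far
  larger).
* Degenerate (constant) blocks: texture energy 1, contrast 0, homogeneity 1,
  heterogeneity 0; patch fields undefined (`NA`), serialised as empty CSV
  fields.
* Per-image seeds in dataset generation are derived as
  `(master + 1000003·k) mod (2³¹−1)`.
* Bootstrap of a constant sample returns a zero-width interval and zero SE.

# Problem sizes used in the checks

The shipped tests and the acceptance script run the pipeline at reduced but
representative scale, chosen to exercise every code path with comfortable
statistical margins: 300–1024 px frames, 3 images per condition (≥ 20–120
selected blocks per group), 4-point parameter sweeps with 4 replicate images
per level, 500-dataset coverage simulations at n = 100 per group with 1 000
bootstrap replicates, and ≥ 10⁴ fuzz cases per brute-force oracle.

# Known limitations

* Block-level pooling ignores within-image correlation; p-values are
  anti-conservative to the extent images differ systematically. Use
  `pooling = "image"` to check robustness.
* Otsu per block adapts the threshold to local range: blocks containing
  only background still split their noise into "patches". In ROI-covering
  blocks with real signal this is immaterial, but an ROI that includes
  large signal-free blocks will contribute noise patches to the counts.
* Patch counts are inflated by clusters straddling block borders (counted
  in each block) and deflated by merged clusters; at the default density
  and size these effects are within ±10%.
* The 45° texture column is not exactly invariant under 90° rotation (see
  above); full invariance holds at 180°.
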