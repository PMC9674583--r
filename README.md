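# stedtex

Block-based patch and texture analysis of super-resolution fluorescence
images.

## The problem

Super-resolution (STED) imaging of extracellular-matrix components such as
hyaluronan resolves signal organisation at the scale of tens of nanometres:
instead of a diffuse stain, the cell periphery shows discrete nanoscale
clusters whose number, size, packing density and spatial texture can differ
between cell states (e.g. normal vs invasive fibroblasts). `stedtex` turns a
set of single-channel intensity images plus expert-drawn region-of-interest
masks into per-block quantitative features and a nonparametric group
comparison, and ships a synthetic image generator with known ground truth so
the entire pipeline can be validated end to end without access to original
microscope data.

Intended users: microscopists and image analysts comparing the nanoscale
organisation of a stained component between two groups of cells.

## The method

Each image is tiled from the top-left into constant 100 × 100-px blocks
(2.5 µm at 25 nm pixels); every block overlapping the markup is analysed.

**Patch statistics** per block: Otsu's threshold (256-bin histogram over the
block's range) binarises the block; 8-connected components are the patches.
Reported: patch count, mean patch area (px), mean foreground intensity, and
the unweighted mean of per-patch mean intensities.

**Texture** per block: after quantisation to *L* = 64 gray levels, gray-level
co-occurrence matrices *p(i, j)* are formed at twelve offsets (distances
1–4 at 0°, 45°, 90°), symmetrised and normalised. Per GLCM:

    energy      = Σᵢⱼ p(i,j)²
    contrast    = Σᵢⱼ (i−j)² p(i,j)
    homogeneity = Σᵢⱼ p(i,j) / (1 + (i−j)²)

Each feature's 4 × 3 distance-by-angle matrix is reduced to a single
rotation/offset-robust scalar by its leading singular value (scaled by
1/√12 so a constant matrix is a fixed point), and
heterogeneity = 1 − homogeneity.

**Inference** per feature, pooling all selected blocks of a group:
Mann–Whitney U (exact two-sided p for small tie-free samples, tie-corrected
normal approximation otherwise), bootstrap difference of medians with
percentile 95% CI (10 000 replicates), bootstrap SE of the median, and
notched-box statistics with notches at median ± 2·SE(median).

See the methods vignette (`vignettes/block-texture-methods.Rmd`) for
assumptions, parameter rationale and limitations.

## Worked example

Simulate two small conditions (the invasive-like preset has twice the
cluster density, 1.5× the cluster radius and 0.7× the peak intensity of the
control preset), extract per-block features and compare:

```r
library(stedtex)

dir <- tempfile("sted_demo_")
cfg <- pipeline_config(n_boot = 5000, seed = 42)
res <- run_pipeline(dir,
                    control  = preset_spec("control", 512, 512),
                    invasive = preset_spec("invasive", 512, 512),
                    n_per_group = 2, config = cfg, seed = 42)
print(res$comparison)
```

```
Group comparison: control vs invasive (block-level pooling, 5000 bootstrap replicates)

                  feature median a median b      diff             95% CI   U        p sig
              patch_count  9.50000 15.50000  -6.00000          [-11, -1]  69 3.99e-04 ***
       mean_patch_area_px 34.47000 66.36000 -31.89000    [-43.3, -22.24]   5 2.76e-10 ***
        mean_fg_intensity 78.44000 70.40000   8.03800    [-1.067, 18.43] 297 8.00e-03  **
 mean_intensity_per_patch 74.31000 61.32000  12.99000     [4.887, 21.87] 361 2.40e-06 ***
                   energy  0.09665  0.04603   0.05063 [0.02928, 0.08459] 370 4.07e-07 ***
                 contrast 20.54000 30.07000  -9.53800    [-16.89, -4.83]  61 7.94e-05 ***
            heterogeneity  0.43730  0.55160  -0.11420 [-0.165, -0.07184]  28 2.64e-07 ***

Signif.: *** p<0.001, ** p<0.01, * p<0.05
```

Reading the table: `diff` is `median(control) − median(invasive)` with its
bootstrap percentile CI. The invasive-like condition shows more patches per
block (9.5 → 15.5), larger patches (34 → 66 px), higher contrast and
heterogeneity, and lower energy and per-patch intensity — i.e. the signal is
assembled into more, larger, less densely packed clusters with a more
heterogeneous texture. `plot(res$comparison)` draws the corresponding
notched box plots (thin red line = median; notches = ±2 SE of the median).

The per-block feature table is in `res$features` and on disk
(`features.csv`); run on real data via `read_labels()` + `run_extract()` +
`run_compare()`, or the CLI script `inst/scripts/stedtex`
(`simulate` / `extract` / `compare` / `all` subcommands).

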