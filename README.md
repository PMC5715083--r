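# glandbam

Morphometric grading of colorectal tissue from gland segmentation masks,
built around the **Best Alignment Metric (BAM)** — a shape-space distance
between planar closed curves.

Colorectal adenocarcinoma is graded by the degree of gland formation: normal
colonic crypts appear in section as near-elliptical rings, and their
boundaries deform progressively with tumour grade. `glandbam` turns that
observation into numbers. It is intended for image-analysis researchers and
computational pathologists who already have gland segmentations (label
masks) and want reproducible, shape-based grading features on top of them.

## The method

For two closed curves represented by N equally spaced, zero-mean points
(as complex numbers `u_j`, `v_j`), the BAM distance between their shape
classes is

    d([u],[v]) = sqrt( (1/N) * min_{r, theta} sum_j | v_j - e^{i theta} u_{j+r} |^2 )

minimized over all cyclic shifts `r` and rotations `theta` — i.e. the curves
are implicitly aligned before they are compared. For each shift the optimal
rotation is closed-form, and all shifts are handled at once by an FFT
cross-correlation, giving O(N log N) per distance; a brute-force grid oracle
verifies the fast path in the tests.

The **glandular aberrance** of one gland is the BAM distance between its
boundary and a circle, computed on a level playing field:

1. fit the minimum-area enclosing ellipse (MVEE) of the boundary and apply
   the affine "whitening" map that turns that ellipse into a circle — this
   removes the anisotropy of an oblique cut through the tubular gland;
2. normalize both curves to N points, unit perimeter, zero mean;
3. the aberrance is the BAM distance between the two normalized shapes.

Ellipses of any pose and axis ratio score ≈ 0; deformed glands score up to
~0.1. Per image, the package computes the **mean BAM**, the **BAM entropy**
(Shannon entropy of the aberrance histogram, bin width 0.015) and the
**Regularity Index** (fraction of glands in the first two bins), removes the
artifacts that inflate normal images (small tangential crypt sections,
border-clipped glands), and grades images with an RBF-kernel SVM under
repeated stratified 3-fold cross-validation (accuracy, per-class
precision/recall/specificity/F1, ROC/AUC, Kruskal–Wallis group test).

A synthetic mask generator with grade-controlled boundary deformation makes
the whole pipeline testable end-to-end without any external data.

## Worked example

```r
library(glandbam)

# a synthetic high-grade image: 512 px, ~12 strongly deformed glands
cfg <- synthetic_config(image_size = c(512L, 512L), n_glands = c(10L, 14L), seed = 42L)
set.seed(42)
img <- generate_image_mask("high_grade", cfg, "hg_example")

records  <- image_aberrance_table(img$mask, "hg_example")
head(as.data.frame(records)[, c("gland_id", "area", "touches_border", "aberrance")], 5)
#>   gland_id area touches_border  aberrance
#> 1        1 6684          FALSE 0.04856817
#> 2        2 7209          FALSE 0.03399166
#> 3        3 7342          FALSE 0.04360958
#> 4        4 6712          FALSE 0.01928674
#> 5        5 7086          FALSE 0.02507030

compute_image_features(records, label = "high_grade")
#>    image_id n_glands mean_bam bam_entropy regularity_index      label postprocessed
#>  hg_example       10   0.0445        1.37              0.3 high_grade         FALSE
```

Each gland's aberrance (0.02–0.05 here) sits well above the ~0.001 of a
normal, near-elliptical gland; consequently the image's mean BAM is high,
its aberrance histogram is spread out (entropy 1.37 nats), and only 30% of
glands fall in the two lowest bins (Regularity Index 0.3) — the signature of
a high-grade image. A normal image shows mean BAM ≈ 0.001–0.003, entropy
near 0 and Regularity Index near 1.

For a full run — masks in, `glands.csv` / `features_pre.csv` /
`features_post.csv` / `report.json` out:

```r
run_pipeline("masks/", "labels.csv", config = NULL, out_dir = "out/")
```

or from a shell via the thin CLI (`inst/cli/glandbam.R`) with subcommands
`synth`, `aberrance`, `features`, `grade`, `postprocess-mask`, `run`.

## Package layout

| Where | What |
|---|---|
| `R/curves.R`, `R/mvee.R` | curve primitives, normalization, MVEE (Rcpp kernel in `src/`), whitening, baseline shape features |
| `R/bam.R` | fast BAM, optimal alignment, brute-force oracle |
| `R/contours.R`, `R/aberrance.R` | mask I/O, sub-pixel contour extraction, per-gland aberrance, probability-map postprocessing |
| `R/features.R` | BAM histogram, entropy, Regularity Index, feature postprocessing |
| `R/grading.R` | SVM grading, repeated stratified CV, metrics, ROC, Kruskal–Wallis |
| `R/synthetic.R` | grade-controlled synthetic mask generator |
| `R/pipeline.R` | configuration, label files, end-to-end `run_pipeline()` |
| `vignettes/glandular-aberrance.Rmd` | the methods vignette: model, assumptions, numerical choices, limitations |

All pixel coordinates are 0-based with x = column and y = row (y increases
downward); counter-clockwise means positive shoelace area in that frame.
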