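---
title: "Quantifying subcellular RNA distributions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subcellular RNA distributions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdindex)
```

## The problem

Single-molecule fluorescence in situ hybridization (smFISH) shows *where*
RNA molecules sit in a cell, but comparing localization across cells,
genes or conditions needs numbers, not pictures. Compartment-based
scoring (e.g. "fraction of spots in the leading edge") is subjective in
cells without crisp anatomical boundaries and collapses gradual
concentration gradients into a binary call. `rdindex` instead summarises
an RNA channel with three intensity-weighted spatial statistics computed
against the segmented cell and nucleus, so that any cell with a usable
cell stain and nuclear stain can be scored automatically and
reproducibly.

## The model

Work on the maximum-intensity z-projection. Let $I_{ij} \ge 0$ be the RNA
intensity of pixel $(i,j)$ after background handling, restricted to the
cell mask. Pixel centers sit at integer coordinates, origin top-left.
The package deliberately does **not** detect discrete RNA spots: pixel
intensities are the observable, which keeps the method usable for
abundant species and poly(A) stains where spot calling is unreliable. On
synthetic images of unit-intensity spots the intensity-weighted indexes
agree with spot-coordinate versions to better than 1% (tested).

With the intensity-weighted RNA centroid
$(\bar{x}_{RNA}, \bar{y}_{RNA})$, the unweighted cell-mask centroid
$(\bar{x}_{cell}, \bar{y}_{cell})$ and the cell's radius of gyration
$Rg_{cell}$ (root-mean-square distance of all cell-mask pixels to the
cell centroid):

**Polarization index.**
$$PI = \frac{\sqrt{(\bar{x}_{RNA}-\bar{x}_{cell})^2 +
(\bar{y}_{RNA}-\bar{y}_{cell})^2}}{Rg_{cell}}$$
Dimensionless displacement of the RNA mass off the cell center,
normalized for cell size and elongation. 0 for any centrally symmetric
distribution.

**Second moment.** For a center $c$,
$$\mu_2(c) = \sum_{ij} r_{ij}^2 \frac{I_{ij}}{\sum_{ij} I_{ij}},$$
with $r_{ij}$ the Euclidean distance of pixel $(i,j)$ to $c$.

**Dispersion index.** $DI = \mu_2(\text{RNA centroid}) /
\mu_2^{unif}(\text{cell centroid})$, where the uniform reference assigns
equal intensity to every cell-mask pixel. Diffuse RNA gives $DI = 1$;
concentration anywhere gives $DI < 1$; peripheral accumulation gives
$DI > 1$ (but the value is confounded by polarization).

**Peripheral distribution index.** Same ratio with *both* moments taken
about the nucleus centroid:
$PDI = \mu_2(\text{nucleus centroid}) / \mu_2^{unif}(\text{nucleus
centroid})$. Taking the reference about the same point is the only
normalization under which a diffuse RNA gives exactly 1 wherever the
nucleus sits, and it makes the index invariant to relocating RNA mass at
fixed distance from the nucleus centroid — i.e. insensitive to
polarization, which PI captures. $PDI < 1$ is perinuclear, $> 1$
peripheral.

In the implementation the uniform reference is evaluated through the
same code path as the numerator, so the diffuse anchors hold to machine
precision, not merely to a tolerance.

Also reported per cell: the mean RNA intensity (raw channel summed over
the cell mask divided by pixel count — computed *before* background
thresholding, since it is a signal-level diagnostic, not a distribution
statistic) and the cell area in µm² when pixel-size metadata exists
(pixel units with a warning otherwise; the indexes themselves are
dimensionless and unaffected).

## Segmentation

The cell mask follows the classical edge-based recipe: optional
adaptive-denoise/sharpen pre-processing, 3×3 Sobel gradient magnitude,
binarization, one 1-pixel dilation (3×3 square: "one pixel in all
directions" includes diagonals), flood fill of interior holes
(4-connected background from the border), and retention of the largest
8-connected component — one cell per image, with other cells cropped or
edited away. The nuclear mask is Wiener-denoised, Otsu-thresholded,
intersected with the cell mask (discarding neighbours' nuclei) and
hole-filled; it is contained in the cell mask by construction.

Three numerical choices were genuinely open and are fixed as follows:

* **Automatic edge threshold.** The base threshold is
  $4 \times \mathrm{RMS}(\text{gradient})$, a standard automatic Sobel
  heuristic; the user-facing `edge_threshold_multiplier` (default 0.5)
  scales it. Lower multipliers provably detect a superset of edge
  pixels (property-tested). The constant 4 is an explicit stand-in for
  an unpublished internal heuristic and is exposed as
  `edge_threshold_constant`.
* **Unsharp masking.** Amount 1.0, Gaussian σ 1.0 px — conventional
  defaults; the iteration count is the user's knob.
* **Wiener filter.** 5×5 window; noise power estimated as the image mean
  of the local variances (the classical adaptive-filter default matching
  the described behaviour). Pre-processing of the *cell* channel is off
  by default (`wiener_iterations = 0`); it is listed as a user option,
  not part of the automatic path.

**Known bias.** On a clean step edge the Sobel response occupies one
pixel on each side and the prescribed dilation adds one more, so a
recovered boundary sits ≈2 px outside the true contour. For an
acquisition-scale cell (radius ~150 px) this costs ~3% area and the mask
recovery gate (IoU ≥ 95% against generating truth) passes with margin;
for much smaller cells the relative bias grows. This is a property of
the published recipe, not a tunable.

**Editing.** The interactive polygon tools become pure functions:
`draw` (replace), `limit` (intersect), `expand` (union), `dilate`
(grow 1 px). Edits are data — recorded in the mask's `edit_log`, stored
in the run configuration or a decision file, validated (simple polygons
only) and replayed in listed order, after which the nuclear mask is
recomputed. An entire human-reviewed analysis is thus reproducible from
artifacts on disk; there is no GUI event loop.

## Background handling

Two readings of "background removal" coexist in practice and both are
implemented. The default, **threshold** mode zeroes pixels at or below
the user level and keeps survivors at full value; **subtract** mode
subtracts the level and clips at zero. The mode and level are recorded
in every output row. The `threshold_sweep()` utility (and the
`sweep-threshold` CLI subcommand) recomputes the indexes over a level
grid: with a low-abundance RNA the background dominates total intensity,
pulling PDI toward 1; raising the level moves PDI monotonically toward
the signal's own value, where the curve plateaus — the recommended way
to choose a per-channel level (typically 5–15% of the dynamic range when
acquisition conditions are stable). Degenerate fields (nothing above
background) are flagged rows, never silent NaNs and never a batch abort.

## The synthetic world

`synthetic_cell_spec()` defaults state the world the tests run in: a
512×512, 12-bit frame with 0.16 µm pixels (a 63× confocal objective), a
disk cell of radius 150 px containing a 40 px nucleus offset 30 px, a
nuclear stain at 75% and cell stain at 40% of the dynamic range. RNA is
laid down per class — `uniform`, `perinuclear(σ)`,
`peripheral_rim(inner_frac)`, `polarized(direction,
displacement_frac)`, `clustered(n, σ)` — quantized to the bit depth,
optionally under a uniform noise floor or Gaussian noise, with one
seeded RNG stream per image (identical spec + seed is bit-identical;
tested). Where a closed form exists the truth record carries it: uniform
⇒ DI = PDI = 1, PI = 0; a polarized blob displaced by fraction $d$ of
the disk radius ⇒ PI = $d\sqrt{2}$, since a uniform disk of radius $R$
has $Rg = R/\sqrt{2}$.

The noise-sweep fixture mimics a low-abundance peripheral transcript: 40
diffraction-limited spots (σ 1.2 px, peak ≈ 3000 of 4095) on the
0.85–0.95 R annulus over a uniform floor on [0, 400] (~10% of range).
Measured once and frozen as the acceptance expectation: PDI ≈ 1.04 at
threshold 0, monotone rise, plateau ≈ 1.54 above the noise level.

What a green test does **not** establish: the generator renders flat
two-level stains and isotropic noise — no amplification chemistry, no
optical aberration, no uneven illumination, and strictly 2-D geometry.
In real spread cells the projected cytoplasmic volume thins toward the
periphery, so even a freely diffusing RNA scores PDI and DI below 1 in a
well-spread cell and near 1 in a rounded one. Absolute index values must
therefore be interpreted against the 3-D morphology of the cells at
hand (cell area is reported as a coarse indicator, and the poly(A)
population makes a good internal reference); between-condition
comparisons are safest at matched morphology.

## Worked example

```{r example}
spec <- synthetic_cell_spec(rna_class = list(type = "peripheral_rim",
                                             inner_frac = 0.8),
                            seed = 42)
g <- generate_synthetic_cell(spec, source_id = "demo")
proj <- max_project(g$image)
cm <- cell_mask(channel(proj, "cell"))
nm <- nuclear_mask(channel(proj, "nucleus"), cm)
compute_rdi(proj, cm, nm)[, c("rna_role", "pdi", "pi", "di", "area_um2")]
```

The localized channel carries the rim (PDI and DI well above 1, PI near
0: peripheral but unpolarized); the control channel is uniform (all
three anchors near their diffuse values — not exactly, because the
*recovered* mask differs from the generating one by the ~2 px boundary
bias discussed above; with the generating masks the anchors are exact).

## Limitations

* One cell per image (the largest component); multi-cell fields need
  cropping or `limit` edits.
* Uncompressed TIFF only; vendor formats are converted upstream.
* 2-D only: all indexes are computed on the maximum projection, and the
  3-D caveat above applies to their interpretation.
* No spot detection, by design; absolute RNA counts are out of scope.
* Downstream statistics (ANOVA, t-tests across conditions) are left to
  dedicated tools; this package produces the per-cell measurements.
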