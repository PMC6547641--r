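# rdindex

Quantitative description of subcellular RNA distributions from
multichannel fluorescence microscopy.

Single-molecule RNA in situ hybridization (smFISH) images tell you where
a transcript sits in a cell; `rdindex` turns that into numbers that can
be compared across cells, genes and conditions. It reads 4-channel TIFF
images (nuclear stain, whole-cell stain, one or two RNA channels),
segments the cell and nucleus, lets you correct the masks with scripted,
replayable polygon edits, and reports three intensity-weighted spatial
indexes per RNA channel plus mean RNA intensity and cell area, exported
as CSV. It is aimed at labs quantifying RNA localization in cultured
cells — fibroblasts, migrating mesenchymal cells, anything without crisp
anatomical compartments — where compartment-based scoring is subjective.

## The statistics

With $I_{ij}$ the RNA intensity of pixel $(i,j)$ inside the cell mask
(above a user background threshold), and
$\mu_2(c) = \sum_{ij} r_{ij}^2\, I_{ij} / \sum_{ij} I_{ij}$ the
intensity-weighted second moment about a point $c$:

* **Polarization index** —
  $PI = \lVert \text{RNA centroid} - \text{cell centroid} \rVert / Rg_{cell}$,
  with $Rg_{cell}$ the root-mean-square distance of cell-mask pixels to
  the cell centroid. 0 for symmetric distributions.
* **Dispersion index** —
  $DI = \mu_2(\text{RNA centroid}) / \mu_2^{unif}(\text{cell centroid})$,
  the reference being a uniform distribution over the cell mask.
  1 = diffuse, < 1 = concentrated, > 1 = peripheral.
* **Peripheral distribution index** —
  $PDI = \mu_2(\text{nucleus centroid}) / \mu_2^{unif}(\text{nucleus centroid})$.
  1 = diffuse, < 1 = perinuclear, > 1 = peripheral; invariant to
  polarization (both moments about the same point), which PI captures.

Segmentation follows the classical recipe: Sobel gradient → automatic
threshold × user multiplier (default 0.5) → 1-px dilation → flood fill →
largest component for the cell; Wiener denoise → Otsu → restrict to cell
→ flood fill for the nucleus. Masks are editable (`draw`, `limit`,
`expand`, `dilate`) and every edit is data, so a reviewed analysis
replays exactly.

## Worked example

A synthetic 512×512 cell (disk radius 150 px, nucleus offset from
center) whose "localized" RNA channel is a peripheral rim and whose
"control" channel is uniform:

```r
library(rdindex)
spec <- synthetic_cell_spec(rna_class = list(type = "peripheral_rim",
                                             inner_frac = 0.8),
                            seed = 42)
g    <- generate_synthetic_cell(spec, source_id = "demo")
proj <- max_project(g$image)
cm   <- cell_mask(channel(proj, "cell"))
nm   <- nuclear_mask(channel(proj, "nucleus"), cm)
compute_rdi(proj, cm, nm)[, c("rna_role", "pdi", "pi", "di", "area_um2")]
#>        rna_role       pdi pi        di area_um2
#> 1 rna_localized 1.4569846  0 1.4923337 1871.462
#> 2   rna_control 0.9693148  0 0.9669412 1871.462
```

The rim channel scores PDI ≈ 1.46 and DI ≈ 1.49 — peripheral — with
PI = 0 (unpolarized). The uniform control sits near the diffuse anchor
of 1 for both (within ~3%, the footprint of the segmented mask being
slightly larger than the generating disk; with the generating masks the
anchors are exact to machine precision). Areas are in µm² because the
synthetic images carry 0.16 µm pixel metadata.

Batch analysis over a directory, from R or the CLI:

```r
cfg <- run_config(inputs = "images/*.tif",
                  channel_roles = c("nucleus", "cell",
                                    "rna_localized", "rna_control"),
                  background_thresholds = c(rna_localized = 600,
                                            rna_control = 400),
                  output_dir = "out", overlay = TRUE)
rdi_run(cfg)          # writes out/results.csv, overlays, out/run.log
```

```sh
Rscript inst/cli/rdindex.R analyze --config=conf.json
Rscript inst/cli/rdindex.R sweep-threshold --config=conf.json --max=600 --step=50
Rscript inst/cli/rdindex.R make-fixtures --dir=fixtures --seed=1
```

`sweep-threshold` emits the PDI-versus-background-threshold response
curve used to pick a noise cutoff: PDI starts near 1 while background
dominates, rises as the threshold removes noise, and plateaus at the
signal's own value.

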