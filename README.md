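# pixcell

Pixel- and cell-level analysis of highly multiplexed tissue images.

Multiplexed imaging technologies — imaging mass cytometry (IMC), MIBI,
multiplexed immunofluorescence (mIF), CODEX — measure tens of protein
markers over a tissue section, one intensity channel per marker. Turning
those channels into biology requires a chain of steps that are usually
scattered across several tools: normalisation, tissue/marker masks,
single-cell segmentation, phenotyping, spatial statistics, and
cell-independent area quantification. pixcell implements that chain as
one configurable R pipeline for imaging scientists and computational
biologists who want reproducible, scriptable analyses with every
numerical convention documented and tested.

## What it computes

* **Image input** — reconstruction of images from IMC ablation text files
  (`parse_imc_text`), TIFF stacks in and out (32-bit float, exact
  round-trip), channel metadata as CSV.
* **Normalisation** — percentile rescaling `v -> min(v / P, 1)` with `P`
  the per-channel 99th percentile (configurable, per image or pooled
  across samples).
* **Masks** — Otsu and multi-class Otsu thresholds (256-bin contract),
  Gaussian smoothing, disk dilation/opening, bounded hole filling, and
  boolean mask algebra, composed through declarative recipes.
* **Segmentation** — nucleus detection with an equivalent-diameter size
  filter (`2·sqrt(area/π)`), then whole-cell expansion: radial over a
  membrane mask, seeded watershed of the distance surface, or isotropic;
  contested pixels go to the nearest nucleus, ties to the lower label.
  External label images (e.g. deep-learning segmenters) plug in directly.
* **Phenotyping** — compartment and type assignment by mask-overlap
  fractions (inclusive boundaries), boolean threshold gates
  (`"CD8 >= 0.01 & PD1 >= 0.005"`), and unsupervised clustering:
  z-score → PCA → kNN graph → Louvain at a chosen resolution.
* **Spatial statistics** — homotypic aggregation with DBSCAN
  (`eps = sqrt(min_points / (π·density))` when derived from a density
  floor), nearest heterotypic centroid distances, two-sided Wilcoxon
  group comparisons with BH correction and an effect-size relevance rule
  (`|Δmedian| ≥ 8 µm`, FDR < 0.1), and a within-sample permutation null
  (`p = (1 + #{|null| ≥ |obs|}) / (K + 1)`).
* **Pixel-level areas** — marker-positive fractions of boolean mask
  expressions over image or compartment denominators.
* **Synthetic tissue** — a generator with exact ground truth (disk cells,
  zero-truncated Gaussian expression, grouped samples with a planted
  distance shift) used by the whole test suite; no downloads needed.

The methods vignette (`vignettes/pixcell-methods.Rmd`) documents every
model, parameter and numerical convention.

## Worked example

Generate a small synthetic tissue with two cell types, segment it, gate
the phenotypes, and quantify the IgA-positive area:

```r
library(pixcell)

chans <- channel_metadata(c("DNA1", "CD3", "IgA"),
                          role = c("nucleus", "marker", "marker"))
spec <- tissue_spec(
  image_size = c(120, 120), pixel_size_um = 1, channels = chans,
  cell_types = list(
    list(name = "T_cell", count = 8, radius_px = 4, nucleus_radius_px = 2,
         expression = list(DNA1 = 1, CD3 = 0.8, IgA = 0.02),
         expression_sd = 0.03),
    list(name = "IgA_cell", count = 8, radius_px = 4, nucleus_radius_px = 2,
         expression = list(DNA1 = 1, CD3 = 0.02, IgA = 0.9),
         expression_sd = 0.03)),
  noise_sd = 0.01, seed = 42)
tissue <- generate_tissue(spec)

params <- segmentation_params("DNA1", min_diameter_px = 2,
                              max_diameter_px = 20,
                              expansion = "isotropic", expansion_px = 3)
nuclei <- detect_nuclei(tissue$stack, params)
cells  <- extract_features(expand_cells(nuclei, params), tissue$stack)
nuclei
#> label_image: 120 x 120 px, 16 cell(s)

head(cells[, c("cell_id", "centroid_x_px", "centroid_y_px",
               "area_px", "CD3", "IgA")], 4)
#>   cell_id centroid_x_px centroid_y_px area_px    CD3     IgA
#> 1       1            24             5      73 0.0139 0.61734
#> 2       2           107             6      73 0.5214 0.02066
#> 3       3            72             7      73 0.5524 0.00466
#> 4       4            61            11      73 0.5451 0.02059

typed <- apply_gates(cells, list(gate_spec("T_cell",  "CD3 >= 0.4"),
                                 gate_spec("IgA_cell", "IgA >= 0.4")))
table(typed$cell_type)
#> IgA_cell   T_cell
#>        8        8
```

All 16 planted cells are recovered and typed correctly. The mean CD3 of a
T cell (~0.55) is lower than the planted 0.8 because the expanded cell
(73 px) is larger than the painted disk (49 px) — the usual cytoplasmic
dilution of nuclear-seeded segmentation, which is why gate thresholds are
set on the extracted means, not the staining model.

```r
iga_mask <- threshold_otsu(get_channel(tissue$stack, "IgA"), "IgA")$mask
positive_area(list(IgA = iga_mask), "IgA", "image", tissue$stack$sample_id)
#>          sample_id numerator_expression denominator_name positive_px
#> 1 synthetic_seed42                  IgA            image         392
#>   denominator_px fraction
#> 1          14400   0.0272

d <- nearest_distances(typed[typed$cell_type == "T_cell", ],
                       typed[typed$cell_type == "IgA_cell", ])
median(d$nearest_distance_um)
#> [1] 27.5
```

The 392 IgA-positive pixels are exactly the 8 painted IgA-cell disks
(8 × 49 px), 2.7 % of the image; the median T-cell-to-IgA-cell nearest
distance on this layout is 27.5 µm.

For multi-sample studies, declare samples, recipes, gates and analyses in
a YAML file and run `run_pipeline(validate_config("run.yaml"))` or the
CLI wrapper `inst/cli/pixcell --config run.yaml` — stages can be run
separately and resumed, with byte-identical outputs for identical
configuration and seed.

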