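---
title: "pixcell methods: from multiplexed images to spatial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pixcell methods: from multiplexed images to spatial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pixcell)
```

pixcell analyses highly multiplexed tissue images — imaging mass cytometry
(IMC), MIBI, multiplexed immunofluorescence (mIF), CODEX — as one pipeline:
raw images are normalised, turned into tissue-compartment and marker masks,
segmented into single cells, phenotyped, and finally summarised as
spatially resolved statistics and pixel-level positive-area fractions.
This vignette explains the models and procedures behind each stage, the
parameters that matter, and the choices made where several readings were
defensible.

## Conventions

One coordinate convention is used everywhere: pixels are indexed 0-based
as `(x = column, y = row)` with the origin at the top-left, and every
distance (expansion radii, centroid distances, DBSCAN reachability) is
measured between pixel centres. Physical units enter through a single
`pixel_size_um`; centroids are reported both in pixels and micrometres.
Connectivity is 4-connected throughout (component labelling, hole
filling, cell pixel sets), which keeps cells disjoint under every
expansion strategy.

## Image input and normalisation

IMC ablation text files (tab-delimited rows of `X`, `Y` and one intensity
column per channel) are rebuilt into a rectangular image of size
`(max Y + 1) x (max X + 1)`; pixels missing from the file — truncated
ablations are common — are filled with 0 and counted in a warning, because
downstream morphology needs rectangular grids. Header tokens such as
`"CD3(Er170Di)"` are matched to the channel table by substring against
the marker name or the metal label; an ambiguous match (e.g. `CD3`
against both `CD3(...)` and `CD33(...)`) is an error rather than a guess.

Channel intensities are normalised by the *percentile rescaling* rule:
each value `v` becomes `min(v / P, 1)`, where `P` is the chosen
percentile (default the 99th) of the channel's pixel distribution,
computed with linear interpolation between order statistics. Values above
`P` are clipped to 1, so normalised stacks live in `[0, 1]` and
thresholds downstream stay on one scale. Two scopes are exposed because
both occur in practice: `per_image` (default; each sample normalised on
its own distribution) and `pooled_across_samples` (one `P` per channel
over all samples' pixels, appropriate when absolute intensities must stay
comparable across a batch acquired together).

## Thresholding and mask recipes

Otsu thresholding uses a fixed, documented contract: a 256-bin histogram
of the channel's observed range, the threshold maximising between-class
variance placed at the upper edge of the last background bin, and
"positive" meaning *strictly greater* than the threshold (so an all-zero
background never turns positive at `t = 0`). The multi-class variant
maximises the multi-class between-class variance over all split
combinations and keeps the top `classes - background_classes` classes;
with 2 classes and 1 background class it reduces exactly to the
single-threshold case. The bin count is part of the contract: published
pipelines differ silently on it, so pixcell fixes 256 and tests the
maximiser against an exhaustive scan.

Masks are produced by *recipes*: an ordered step list applied to channel
or mask sources. A channel source may first be smoothed (isotropic
Gaussian, standard deviation in pixels, kernel truncated at four standard
deviations and renormalised, symmetric reflective boundary) and must then
be thresholded before any morphological or boolean step; mask sources are
used as-is; multiple sources are combined with an explicit `union`. The
morphological vocabulary is deliberately small:

* `dilate(radius_px)` / `opening(radius_px)` with a disk structuring
  element rasterised as all pixels whose centre lies within `radius` of
  the centre pixel;
* `fill_holes(max_area_px)`: background components (4-connected) of area
  *strictly below* the cutoff that do not touch the image border are
  filled — "negative areas" inside tissue are holes, while
  border-touching background is genuine outside and is never filled;
* `subtract(mask)` / `intersect(mask)` against previously defined masks.

This vocabulary is sufficient to express, verbatim, compound recipes of
the kind used for gut mucosa: a lamina-propria mask from a thresholded
structural channel with `<75`-px holes filled; an epithelial mask built
from two thresholded epithelial channels, unioned, dilated by a 3-px
disk, hole-filled, cleaned with a 150-px opening and finally subtracted
from the lamina mask; and a marker mask from a 1.5-px Gaussian smooth
followed by three-class Otsu with two background classes.

## Segmentation

Nuclei are detected by thresholding the nuclear channel (Otsu or a fixed
value), labelling 4-connected components and keeping those whose
*equivalent diameter* `2 * sqrt(area / pi)` lies within the configured
bounds (inclusive); typical bounds are 4–60 px at IMC/mIF resolutions.
Survivors are renumbered in raster order of their topmost-leftmost pixel
so labels are reproducible. Touching nuclei are *not* split: declumping
is deliberately out of scope (see Limitations), and a labelled image from
any external segmenter — including deep-learning tools — can be supplied
in its place and flows through feature extraction unchanged.

Whole cells are obtained from nuclei by one of three expansions, all
sharing three guarantees: every nucleus pixel keeps its label, cells are
pairwise disjoint, and a contested pixel joins the *nearest* nucleus
(Euclidean distance to the nearest pixel of the nucleus, compared in
exact integer arithmetic), with exact ties resolved to the lower label so
output is independent of traversal order.

* `radial(max_px)`: growth up to `max_px`, permitted only into
  membrane-positive pixels — the most restrictive reading of expanding
  "over a membrane mask";
* `watershed`: seeded flooding of the distance-to-nearest-nucleus
  surface restricted to nucleus-or-membrane pixels, for membranes that
  form closed regions rather than thin rims;
* `isotropic(px)`: unconstrained nearest-nucleus growth by a fixed
  distance (e.g. 5 px), as used for densely packed tissue microarrays.

Per-cell features are the pixel count, the unweighted centroid of pixel
centres, and the arithmetic mean of each channel over the cell's pixels.
Gates and cluster analyses operate on these mean intensities.

## Phenotyping

**Overlap rules.** A cell belongs to a compartment when the fraction of
its own pixels inside the compartment mask is at least the configured
minimum ("at least 30 %" is inclusive: 3 of 10 pixels at a 0.30 cutoff
qualifies). Cell typing by marker masks computes every rule's overlap
fraction, keeps the rules whose own minimum is met, and assigns the type
with the highest fraction; exact ties go to the first-listed rule and are
counted in a message. Denominators are always the cell's area, never the
mask's.

**Gates.** Gates are boolean expressions over mean intensities
(`"CD8 >= 0.01 & PD1 >= 0.005"`) parsed into an abstract syntax tree and
checked against a whitelist (`>`, `>=`, `<`, `<=`, `&`, `|`, `!`,
parentheses, channel names, numbers) before evaluation — unknown names
and any other function are errors, so configuration files cannot execute
code. A gate may nest inside a parent gate, in which case it sees only
the parent's cells. All comparison boundaries are inclusive exactly as
written.

**Clustering.** Cells are optionally z-scored per marker (constant
markers dropped with a warning), projected onto principal components
(signs fixed so the largest-magnitude loading of each component is
positive, making the projection deterministic), connected in a k-nearest-
neighbour graph symmetrised by union with unit edge weights, and
partitioned with the Louvain modularity algorithm at a user-set
resolution under a fixed seed. Cluster ids are renumbered by descending
size. Two practical notes: `k_neighbours` (default 20) should stay below
the smallest population you expect to resolve, otherwise the graph is
forced to link across populations and small clusters blur into their
neighbours; and resolution interacts with `k` — with `k = 20`,
resolutions around 0.3–0.8 recover well-separated populations, while
small `k` at high resolution over-fragments. The per-cluster profile
table reports mean *raw* intensities, so profiles remain interpretable
on the original scale.

The optional 2-D embedding for reporting is the first two principal
components of the same feature matrix with the same sign convention: a
deterministic linear projection, reproducible across machines, intended
only to visualise cluster structure.

## Spatial statistics

**Homotypic aggregation** uses DBSCAN on the centroids (in µm) of cells
of one type. The reachability radius can be given directly or derived
from a density floor: a disk of radius `eps` containing `min_points`
cells at exactly the stated density gives
`eps = sqrt(min_points / (pi * density))`; the defaults `min_points = 5`
and 5 cells/mm² yield `eps ≈ 564 µm`. One deviation from textbook DBSCAN
is documented: border points join the cluster of their *nearest* core
point (ties by core coordinates) instead of the first cluster to reach
them, making the labelling invariant to input order up to renumbering —
a property the test suite checks by permutation.

**Heterotypic distances** are Euclidean centroid distances from every
source-type cell to its nearest target-type cell within the same sample;
a cell present in both sets never matches itself. A strict proximity
cutoff (default 12 µm, twice a 6-µm maximal cell radius) classifies
sources as proximal or distal.

**Group comparisons** pool cell-level distances per sample group and use
the two-sided Wilcoxon rank-sum test in its tie-corrected normal
approximation with continuity correction (cell-level sample sizes are
large; a per-sample-median mode is available but off by default),
followed by Benjamini–Hochberg adjustment across the comparison list. A
comparison is *relevant* only when both the effect size and the evidence
pass: `|delta median| >= 8 µm` (about one lymphocyte diameter) and
FDR `< 0.1`.

**Permutation null.** The statistic is the difference in pooled median
nearest distances between the two groups. Under the null that cell
identities carry no positional information, the labels within each
sample are exchangeable: each of `K` permutations (default 10 000)
reshuffles the type labels among *all* cells of a sample — positions
fixed, type counts preserved — and recomputes the statistic. The
two-tailed p-value is `(1 + #{|null| >= |observed|}) / (K + 1)`; the
`+1` keeps p away from zero and makes the estimator valid at any `K`.
Per-sample distance matrices are precomputed once, so a permutation costs
only index bookkeeping. BH adjustment is applied across the set of
comparisons tested together.

## Pixel-level quantification

The positive-area fraction evaluates a boolean expression over masks
pixelwise, intersects it with the denominator region *first*, and
reports `positive_px / denominator_px`. Intersection-first matters: a
marker-positive pixel outside the lamina propria does not count towards
"marker-positive area over the lamina propria". Fractions are unit-free;
areas convert to µm² through `pixel_size_um^2`.

## The synthetic-tissue generator

Every stage is validated on generated tissue with exact ground truth,
so no download is required to test the package. `generate_tissue` places
non-overlapping disk cells (rejection sampling, capped at 10⁴ attempts
per cell) inside rectangular compartments, paints the nuclear channel on
a concentric nuclear disk and each marker channel on the whole cell with
per-cell expression drawn from a zero-truncated Gaussian, and adds
optional Gaussian pixel noise clamped at zero (intensities are
non-negative by construction). Disks centred on pixel centres make every
oracle analytic: the planted centroid *is* the pixel-set centroid, the
area is the lattice-disk count, and on noiseless fixtures extracted mean
intensities equal the planted draws exactly.

`generate_grouped_samples` builds grouped point patterns for the
distance machinery: all positions are i.i.d. uniform, so at zero shift
the type labels are exchangeable and the permutation test must reject at
its nominal rate; with a planted shift `s`, each group-A source is
displaced towards its nearest target by `s` µm, lowering that group's
median nearest distance by about `s` while, under the same seed, every
other coordinate stays identical to the zero-shift draw.

What the generator does *not* emulate — irregular cell shapes, touching
and overlapping cells, channel spillover, illumination gradients,
hot-pixel artefacts, tissue-scale texture — bounds what passing tests
show: they demonstrate that the algorithms implement their contracts
exactly and recover truth under clean conditions, not that segmentation
or typing accuracy will reach the same numbers on real stained tissue.
Parameter choices on real data remain the user's responsibility.

## Validation conditions and numerical choices

The test suite and the acceptance script use desk-scale problem sizes
chosen once: a 280 × 280 px tissue with 75 planted cells (25 per type,
expression separation 25 standard deviations) for recovery checks;
permutation calibration over 500 replicate datasets of 2 samples per
group and 60 cells per sample at `K = 200`; shift detection over 20
replicates of 8 samples per group with a 30-µm planted shift; and 8
samples for the pixel-versus-cell cross-check. Oracle-equivalence checks
run 20 random instances per operation.

Numerical conventions collected in one place: percentiles interpolate
between order statistics; Otsu bins are 256 over the observed range and
ties take the lowest maximising split; Gaussian kernels truncate at 4
standard deviations and renormalise; boundaries reflect symmetrically;
nearest-seed ties go to the lower label (compared as integer squared
distances, so ties are exact); DBSCAN border ties go to the
lexicographically smaller core; cluster ids order by size; degenerate
inputs (constant channels for Otsu, too few distinct values for
multi-class Otsu, empty pixel-area denominators) raise errors naming the
offending object, while empty results that are legitimate outcomes (no
nuclei passing the size filter) warn and return empty containers.

## Limitations

* Touching nuclei are not split; under-segmentation of dense nuclear
  sheets must be handled by an external segmenter supplied as a label
  image.
* The watershed expansion floods a Euclidean distance surface; in
  long, thin membrane corridors a geodesic formulation could assign a
  handful of frontier pixels differently.
* Normalisation offers per-image and pooled scopes only; no
  illumination-field or spillover correction is attempted.
* The permutation test assumes within-sample exchangeability of cell
  identities; gradients of cell density that correlate with type violate
  the null and are better addressed with covariate-adjusted approaches
  outside this package's scope.
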