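---
title: "spotgrid: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spotgrid: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spotgrid)
```

`spotgrid` analyzes spot tables from multiplexed smFISH spatial
transcriptomics: one record per detected mRNA molecule, with gene identity
and 2D coordinates in micrometres. This vignette is the package's own
account of the models it implements, the tunable parameters and their
defaults, the numerical choices, and what the bundled synthetic scenes do
and do not establish.

## Coordinate conventions

All world coordinates are micrometres; x grows rightward and y downward
(image convention). A `raster_mask` anchors a logical matrix in the world
frame: pixel `(i, j)` covers the half-open square starting at
`origin + (index − 1) · pixel_size`, and its *center* sits at
`origin + (index − 0.5) · pixel_size`. Grid binning uses the same half-open
rule, `floor(coordinate / side)` per axis, so every spot belongs to exactly
one square and boundary spots go to the higher-index bin. Spot tables are
2D; a `z` column survives round trips but is ignored (sections are thin
relative to their lateral extent, and all surfaces below are 2D). Gene
identifiers are compared case-sensitively — fly symbols distinguish *svp*
from *Svp*.

## Disk-overlap colocalization

Each molecule of a species is replaced by a disk of diameter `disk_diameter`
(default **4 µm**); overlapping disks of one species merge into a single
union surface, so repeated local detections are not double-counted. For two
species the overlap of their union surfaces defines two asymmetric
proximities (overlap divided by the *other* species' surface) and the
symmetric distance `D = 2 − (prox_1in2 + prox_2in1)`, which is 0 for
perfectly co-localized species and 2 for species without any overlap. A
disk set fully containing the other species' surface gives the contained
species proximity 1 — a direct consequence of the ratio definition.

Numerics: surfaces are computed on a shared raster lattice (cell size
`coloc_resolution`, default **0.1 µm**) rather than by exact polygon
geometry, which keeps the cost linear in spot count at 10^5 spots per gene.
Boundary cells receive an antialiased weight in [0, 1] — a linear ramp one
cell wide on the signed distance from the cell center to the disk edge —
instead of a hard center-in-disk test. The hard test suffers Gauss-circle
lattice fluctuations (~0.6% for a 2 µm radius at 0.1 µm cells), which would
dominate the 1% closed-form tolerance and prevent smooth convergence under
resolution refinement; with antialiasing, halving the resolution moves
areas by well under 0.5%. Overlaps use the cellwise minimum of the two
coverage fields, so identical spot sets still give exactly `D = 0` and
fully separated ones exactly `D = 2`. Exact circle/lens closed forms and a
Monte-Carlo dart oracle are retained in the test suite as independent
checks.

Gene clustering applies Ward linkage (`hclust`, `ward.D2`) to `D` as-is, with
no Euclidean embedding. `D` is not guaranteed Euclidean, so Ward's variance
interpretation is heuristic here; `ward.D2` is the variant equivalent to the
`ward` linkage of the common Python scientific stack operating on a
condensed distance matrix. The published procedure does not state how
clusters were extracted from the dendrogram, so the cut is an explicit user
choice: a cluster count `k` or a height `h`.

## Grid pseudo-bulk

`rasterize_spots()` bins spots into squares of side
`bin_pixels × pixel_size` = 36 × 0.138 = **4.968 µm**, independently per
sample with the binning origin fixed at world (0, 0). (Workflows that tile
several sections into one frame by adding +1000 µm offsets per sample are
reproduced by the per-sample origin, avoiding cross-sample square
collisions; whether the original analysis binned before or after such
offsets is not documented, so this choice is recorded here rather than
claimed.) Counts are conserved exactly; negative coordinates floor toward
−∞. `filter_squares()` keeps squares with total counts **strictly greater
than 3**; `normalize_grid()` rescales each square to a size factor of
**10,000** and applies `log1p` (natural log, the convention of the standard
single-cell toolkits). Normalizing twice is refused as a state error.

## Gene-set signatures

A category's raw score in a square is the summed (by default normalized)
expression of its genes; z-scores are computed per category across **all
squares pooled over samples** with the population (n-denominator) standard
deviation — the procedure's published description speaks of all squares
together, and the pooled/population choice is exposed in code rather than
hidden. A category whose score is constant across squares has no z-scale
and is never assigned. Assignment offers two modes because published
descriptions of this step disagree: the Methods-style strict **hierarchy**
(highest-priority category with z > 1; default, with the body hierarchy
muscle > epithelia > glia > neurons > male reproductive system > fat body >
oenocyte > hemocyte > heart available via `fly_body_gene_sets()`), and an
**argmax** mode (maximal z among those above threshold, hierarchy as
tie-break). Genes may belong to several categories and count in each
(e.g. *FASN2* in both fat body and oenocyte).

## Tissue masks and nearest-nucleus distances

`build_tissue_mask()` renders one abundant marker gene's spots as single
foreground pixels at `pixel_size` (default **0.138 µm/px**) and applies, in
order: Gaussian blur (ksize 5, σ 1; re-binarized at > 0), erosions 5×5 and
4×4 (removing sparse signal), three 50×50 dilations (closing the tissue),
and a final blur. Kernels are solid rectangles; windows use offsets
`−⌊k/2⌋ … k−1−⌊k/2⌋` per axis (the default-anchor convention of common
image toolkits; asymmetric for even sizes — the source recipe does not pin
down anchor semantics), and out-of-image pixels count as background for
both operations. Blur-then-threshold at > 0 equals a 5×5 box dilation since
all kernel weights are positive; the blur is still computed literally.

`nearest_nucleus_distances()` returns, per spot, the Euclidean distance to
the nearest *foreground pixel center* of the nucleus mask — measured to
segmented pixels, not to object boundaries, so spots inside nuclei get
distances of at most half a pixel diagonal rather than clamped zeros. The
implementation is a chunked exact all-pairs minimum; any accelerated
replacement must pass the brute-force oracle test, which is the behavioural
contract. Genes need `min_gene_spots` (default **100**) pooled spots to be
reported. If a tissue mask is supplied, only spots on its foreground enter
the analysis.

`distance_summary()` reports the empirical median and the argmax of a
Gaussian KDE. The default bandwidth is `sd(x) · n^(−1/7)` (`"scott-mode"`):
Scott's factor with the mode-optimal rate exponent. The density-optimal
`n^(−1/5)` rate (available as `"scott"`) undersmooths for argmax
estimation — for a Rayleigh-shaped distance profile at n = 10⁴ the KDE peak
then carries ~7–8% sampling noise, which would swamp the 5% recovery the
test suite demands; the mode-optimal rate is the textbook remedy, and even
so the peak is the least precise statistic the package reports.

`region_specificity()` is the fraction of a gene's spots falling on
foreground pixels of a region mask, per sample and pooled; genes with zero
spots are reported as undefined (`NA`), not 0.

## Nonnegative-lasso label transfer

Each square's expression vector `y` (log-normalized scale, matching the
grid pipeline) is regressed on the single-cell cluster profile matrix under
positivity: minimize `1/(2n) · ‖y − Xw‖² + α·Σw` over `w ≥ 0` with α =
`lasso_penalty` (default **1**). This is the objective scaling of the
standard Python lasso with `positive=True`; no intercept is fitted, and
inputs are not standardized — with the penalty fixed at 1 the scale of the
inputs is part of the method. The solver is cyclic coordinate descent with
closed-form nonnegative soft-threshold updates (tolerance 1e−8); an
independent glmnet fit cross-checks it in the tests. Weights strictly above
`weight_threshold` (default **0.2**) are confident matches; the square takes
the cluster with the largest weight, ties broken by lexical cluster name
order (deterministic, and logged). Fits are per square — the published
wording ("matched with expression profiles of the grid-based squares")
leaves per-square vs per-cluster ambiguous, and per-square is the recorded
decision. `gene_correlation_concordance()` compares modalities by the
Pearson correlation between the strictly-upper-triangle entries of their
gene–gene correlation matrices, excluding (and counting) genes with zero
variance in either modality.

## The synthetic world

`simulate_scene()` draws, per gene in declared order from a single seeded
RNG stream, a Poisson(`expected_spots`) count and positions from a pattern
density restricted to the gene's regions (rejection sampling against the
analytic region shapes — exactness over speed at desk scale):

| pattern | density | parameters (µm) |
|---|---|---|
| `uniform` | flat | — |
| `nucleus_enriched` | Gaussian mixture on nuclei | `sigma` (2) |
| `nucleus_depleted` | flat × well near nuclei | `well_radius` (4), `well_factor` (0.1) |
| `striped` | ∝ 1 + cos(2πu/period + phase) | `period` (25), `phase` (0) |
| `terminal_enriched` | exp decay from a region end | `lambda` (15) |
| `boundary_apical/basal` | exp decay from annulus inner/outer edge | `lambda` (5) |

Every position is jittered by isotropic Gaussian noise of
`jitter_sd` = **0.14 µm**, the platform's localization precision. Background
false positives default to **0** — measured platform specificity exceeds
99%, so contamination is opt-in (`background_rate` in spots/µm²). Nuclei are
rendered as filled circles into the nucleus mask, matching the black-white
segmentation image the localization stage consumes. Identical `(spec,
seed)` pairs are byte-identical.

No quantitative stripe contrast or terminal-enrichment amplitude is
published; the defaults above are free parameters of this package, chosen
once to look like the qualitative descriptions (µm-scale localization
precision, tens-of-µm banding) and frozen.

`fly_body_scene()` is the canned six-region body section: muscle (striped
*Act88F*/*Mhc* in antiphase, nucleus-enriched *sls*, nucleus-depleted
*TpnC4*, terminal-enriched *Strn-Mlck*, uniform *CG32121*), a gut annulus
with apical/basal *alphaTry*/*betaTry* plus *grh*, and brain, fat, heart,
epithelia regions with exclusive uniform markers. Two density choices are
deliberate: (1) sarcomeric transcripts are set to realistic abundance
(60,000 expected spots for *Act88F*/*Mhc*, 20,000 for *TpnC4*) because the
morphology recipe erodes at 0.138 µm/px and only closes into a solid tissue
mask in that density regime — at ten-fold sparser signal the eroded marker
blanket disintegrates and the mask orphans a third of the *sls* spots;
(2) the scene's gene sets for signature scoring use the broadly distributed
exclusive markers per region, not the subcellularly localized genes — the
same reason field workflows score tissue signatures with robust markers
rather than patchy transcripts.

What a green synthetic test establishes: the algorithms implement their
definitions (binning, metric limits, morphology, distances, regression) and
recover planted structure under clean conditions. What it does not: real
sections have segmentation errors, optical crowding, density gradients,
batch effects between sections and imperfect marker specificity — none of
which the generator emulates. Dataset-level published figures (hundreds of
thousands of squares, cross-modality r ≈ 0.7 against a real single-nucleus
atlas) are therefore out of reach at desk scale by construction.

## Degenerate inputs and edge cases

Empty spot tables rasterize to empty grids (not errors); empty spot sets
have *undefined* disk surfaces (error — proximity denominators would be 0);
genes without spots are excluded from the distance matrix and logged;
an empty nucleus mask is an error; an empty marker set yields an empty
tissue mask with a warning; zero-spot genes get `NA` specificity; constant
score vectors are never assigned; double normalization is refused.

## File formats

Spot tables are delimited text with configurable column names; masks are
single-channel PNG or plain-text ASCII PGM/PBM with a YAML sidecar for
`pixel_size`/`origin` (no TIFF reader exists in the supported dependency
set); count grids export as Matrix Market plus `genes.tsv`/`squares.tsv`
sidecars or dense TSV — real-valued matrices are written at 17 significant
digits so round trips are exact at double precision; configs, gene sets and
scene specs are YAML.
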