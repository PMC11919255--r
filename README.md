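# spotgrid

Analysis of single-molecule spatial transcriptomics **spot tables** — the
per-molecule records `(gene, x, y)` in micrometres produced by multiplexed
smFISH platforms such as Molecular Cartography. These instruments localize
individual mRNA molecules at ~0.14 µm precision across whole tissue sections
(e.g. adult *Drosophila* body and head slices), and most of the downstream
science — which genes occupy which tissue, how transcripts distribute around
nuclei, how spatial data align with single-cell references — can be computed
directly from the spot table without segmenting cells. `spotgrid` implements
that toolkit for R, together with a seeded synthetic-scene generator so that
every stage is testable without any external download.

## What it computes

**Disk-overlap colocalization.** Every molecule of a species becomes a disk
of fixed diameter *d* (default 4 µm); overlapping disks of one species merge
into a single union surface. For species 1 and 2,

```
Proximity_1in2 = Overlap_1,2 / Surface_2
Proximity_2in1 = Overlap_1,2 / Surface_1
Distance_1,2   = 2 − (Proximity_1in2 + Proximity_2in1)
```

so perfectly co-localized species are at distance 0 and species without any
overlap at distance 2. The gene–gene distance matrix feeds Ward hierarchical
clustering to extract groups of co-expressed genes.

**Grid pseudo-bulk.** Spots are rasterized into squares of
36 px × 0.138 µm/px = 4.968 µm; squares with more than 3 total counts are
kept, scaled to a size factor of 10,000 and log-transformed — a
squares × genes matrix that behaves like single-cell data and can be handed
to any scRNA-seq toolkit.

**Gene-set signatures.** Per-category summed expression is z-scored across
all squares; a square is assigned to the highest-priority category with
z > 1 (a pure arg-max mode is also provided).

**Subcellular localization.** A tissue mask is built from one abundant
marker gene by a fixed binary-morphology recipe (Gaussian blur 5×5 σ=1, two
erosions 5×5 and 4×4, three 50×50 dilations, final blur), then every spot's
Euclidean distance to the nearest segmented nucleus pixel is computed
(exactly — the implementation is contract-tested against the brute-force
all-pairs minimum), with per-gene medians and density peaks for genes with
≥ 100 spots. Marker specificity is reported as the fraction of a gene's
spots falling inside a region mask.

**Label transfer.** Each square's expression vector is regressed on
single-cell cluster mean profiles with a nonnegative lasso
(`1/(2n)·RSS + α·Σw`, α = 1, w ≥ 0); weights > 0.2 are confident matches and
the square takes the cluster with the highest weight. Cross-modality
agreement is summarized by the Pearson correlation between the two
modalities' gene–gene correlation matrices.

## Worked example

```r
library(spotgrid)

b <- fly_body_scene(seed = 1)     # synthetic 6-region fly-body section
b$spots
#> <spot_table> 160280 spots, 14/14 panel genes, 1 sample(s)

grid <- normalize_grid(filter_squares(rasterize_spots(b$spots), 3), 10000)
grid
#> <count_grid> 1670 squares x 14 genes, side 4.968 um, log-normalized

assign_labels(score_gene_sets(grid, b$gene_sets))
#> <square_labels> 1670 squares x 6 categories (normalized scale)
#>   labels (hierarchy): muscle=442, brain=358, gut=345, heart=173, fat=163,
#>                       epithelia=159, unassigned=30

pair <- spots_for_genes(b$spots, c("sls", "TpnC4"))
coloc_distance_matrix(pair, genes = c("sls", "TpnC4"))$distance["sls", "TpnC4"]
#> 0.683   # same tissue, different subcellular pattern: partial overlap

tmask <- build_tissue_mask(spots_for_genes(b$spots, "Act88F"))
prof <- nearest_nucleus_distances(pair, b$nucleus_mask, tmask)
for (p in prof) print(distance_summary(p)[c("median", "density_peak")])
#> sls    n= 2954  median = 0.07 um  peak = 0.07 um   (nucleus-enriched)
#> TpnC4  n=19996  median = 5.47 um  peak = 5.87 um   (nucleus-depleted)

region_specificity(b$spots, b$region_masks$muscle, genes = "TpnC4")
#> pooled fraction 0.9978  # >99% of TpnC4 spots inside the muscle region
```

The numbers read as a biologist would expect: the titin-like transcript
(`sls`) hugs the nuclei (median distance ≈ localization noise), the troponin
transcript is pushed away from them, and muscle markers are > 99% specific
to the muscle region.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "spotgrid.R", package = "spotgrid"))') \
    simulate,rasterize,score --out run1 --seed 1
```

Stages: `simulate`, `rasterize`, `score`, `coloc`, `nucdist`, `specificity`,
`transfer`; outputs land under `--out` with a `manifest.yaml` of digests for
reproducibility.

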