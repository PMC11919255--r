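# Shared fixtures. The fly body scene (default seed) is expensive enough to
# build once per test run and reuse read-only.
.fixture_cache <- new.env(parent = emptyenv())

body_scene <- function() {
  if (is.null(.fixture_cache$body)) .fixture_cache$body <- fly_body_scene(seed = 1)
  .fixture_cache$body
}

body_grid <- function() {
  if (is.null(.fixture_cache$grid)) {
    b <- body_scene()
    .fixture_cache$grid <-
      normalize_grid(filter_squares(rasterize_spots(b$spots), 3), 10000)
  }
  .fixture_cache$grid
}

# three well-separated rectangular regions, three marker genes each:
# the ground truth for Ward cluster recovery
three_group_scene <- function(seed = 11, spots_per_gene = 200) {
  regions <- list(r1 = list(shape = "rect", x0 = 0, y0 = 0, x1 = 40, y1 = 40),
                  r2 = list(shape = "rect", x0 = 60, y0 = 0, x1 = 100, y1 = 40),
                  r3 = list(shape = "rect", x0 = 30, y0 = 60, x1 = 70, y1 = 100))
  genes <- list()
  for (r in names(regions)) for (k in 1:3)
    genes[[paste0(r, "_g", k)]] <- list(regions = r, pattern = "uniform",
                                        expected_spots = spots_per_gene)
  spec <- scene_spec(extent = c(100, 100), regions = regions, genes = genes,
                     pixel_size = 0.5)
  simulate_scene(spec, seed = seed)
}
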