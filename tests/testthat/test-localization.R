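test_that("rectangular erosion and dilation equal the double-loop oracle", {
  set.seed(42)
  for (k in list(c(3, 3), c(5, 5), c(4, 4), c(2, 5))) {
    m <- matrix(runif(30 * 25) < 0.4, 30, 25)
    expect_identical(erode_rect(m, k[1], k[2]), oracle_erode(m, k[1], k[2]))
    expect_identical(dilate_rect(m, k[1], k[2]), oracle_dilate(m, k[1], k[2]))
  }
})

test_that("tissue mask: empty and single-spot inputs give empty masks", {
  pan <- gene_panel("m")
  empty <- make_spots(character(), numeric(), numeric(), panel = pan)
  expect_warning(msk <- build_tissue_mask(empty), "no marker spots")
  expect_equal(sum(msk$mask), 0L)
  # a single pixel cannot survive a 5x5 erosion
  one <- make_spots("m", 10, 10, panel = pan)
  expect_warning(msk1 <- build_tissue_mask(one), "empty after morphology")
  expect_equal(sum(msk1$mask), 0L)
})

test_that("tissue mask of a dense block equals the composed morphology oracle", {
  # >= 1 spot per pixel over a 20 x 20 um block (coarse 0.5 um/px raster keeps
  # the oracle's O(n^2 k^2) double loop affordable)
  cfg <- analysis_config(pixel_size = 0.5)
  xs <- seq(10.25, 29.75, by = 0.5)
  gr <- expand.grid(x = xs, y = xs)
  spots <- make_spots(rep("m", nrow(gr)), gr$x, gr$y, panel = gene_panel("m"))
  msk <- build_tissue_mask(spots, cfg)

  # independent re-composition from literal oracle primitives
  base <- matrix(FALSE, nrow(msk$mask), ncol(msk$mask))
  px <- world_to_pixel(msk, spots$x, spots$y)
  base[cbind(px$i, px$j)] <- TRUE
  g <- dnorm(-2:2); g <- g / sum(g)
  blur <- function(m) {
    conv1 <- function(v) {
      n <- length(v); out <- numeric(n)
      for (o in -2:2) {
        idx <- seq_len(n) + o
        ok <- idx >= 1 & idx <= n
        out[ok] <- out[ok] + g[o + 3] * v[idx[ok]]
      }
      out
    }
    m <- apply(m * 1, 2, conv1)
    t(apply(m, 1, conv1))
  }
  o <- blur(base) > 0
  o <- oracle_erode(o, 5, 5)
  o <- oracle_erode(o, 4, 4)
  for (i in 1:3) o <- oracle_dilate(o, 50, 50)
  o <- blur(o) > 0
  expect_identical(msk$mask, o)

  # the mask covers the block plus the dilation margin on each side
  on <- which(msk$mask, arr.ind = TRUE)
  block_px <- range(px$j)
  # reach per side: 3 dilations of an even 50-kernel (+25 one way, +24 the
  # other) plus the blur halo (2 px each way) minus the erosion bite
  expect_gte(block_px[1] - min(on[, 2]), 70)
  expect_lte(block_px[1] - min(on[, 2]), 80)
  expect_gte(max(on[, 2]) - block_px[2], 70)
  expect_lte(max(on[, 2]) - block_px[2], 80)
})

test_that("nearest-nucleus distances equal the exhaustive all-pairs oracle", {
  set.seed(5)
  # mask whose foreground pixel centers are known exactly
  ps <- 0.2
  m <- matrix(FALSE, 120, 120)
  m[cbind(sample(120, 50, TRUE), sample(120, 50, TRUE))] <- TRUE
  nmask <- raster_mask(m, pixel_size = ps, origin = c(0, 0))
  fg <- foreground_coords(nmask)
  pan <- gene_panel("g")
  spots <- make_spots(rep("g", 1000), runif(1000, 0, 24), runif(1000, 0, 24),
                      panel = pan)
  prof <- nearest_nucleus_distances(spots, nmask, min_gene_spots = 1)
  expect_equal(length(prof$g$distances), 1000L)
  oracle <- oracle_nn(spots$x, spots$y, fg$x, fg$y)
  expect_lt(max(abs(prof$g$distances - oracle)), 1e-9)
})

test_that("distance geometry: exact zero on pixel centers and the 3-4-5 case", {
  ps <- 0.138
  m <- matrix(FALSE, 80, 80); m[1, 1] <- TRUE
  # origin chosen so the single foreground pixel center sits at (0, 0)
  nmask <- raster_mask(m, pixel_size = ps, origin = c(-ps / 2, -ps / 2))
  pan <- gene_panel(c("a", "b"))
  spots <- spot_table(data.frame(gene = c("a", "b"), x = c(0, 3), y = c(0, 4)),
                      pan)
  prof <- nearest_nucleus_distances(spots, nmask, min_gene_spots = 1)
  expect_equal(prof$a$distances, 0)
  expect_equal(prof$b$distances, 5)
  # spots inside nuclei are at most half a pixel diagonal away
  inside <- spot_table(data.frame(gene = "a", x = ps / 3, y = -ps / 3), pan)
  p2 <- nearest_nucleus_distances(inside, nmask, min_gene_spots = 1)
  expect_lte(p2$a$distances, ps * sqrt(2) / 2)
  expect_error(nearest_nucleus_distances(
    spots, raster_mask(matrix(FALSE, 2, 2))), "no foreground")
})

test_that("genes below the pooled spot minimum are excluded from profiles", {
  pan <- gene_panel(c("hi", "lo"))
  df <- data.frame(gene = c(rep("hi", 120), rep("lo", 99)),
                   x = runif(219, 0, 10), y = runif(219, 0, 10))
  m <- matrix(FALSE, 10, 10); m[5, 5] <- TRUE
  prof <- nearest_nucleus_distances(spot_table(df, pan),
                                    raster_mask(m, pixel_size = 1),
                                    min_gene_spots = 100)
  expect_setequal(names(prof), "hi")
  expect_equal(attr(prof, "excluded"), "lo")
})

test_that("distance summaries: median, degenerate peak, Rayleigh mode", {
  expect_equal(distance_summary(c(1, 2, 3))$median, 2)
  allsame <- distance_summary(rep(4.2, 50))
  expect_equal(allsame$density_peak, 4.2, tolerance = 1e-3)
  expect_error(distance_summary(1), "at least 2")
  # mode of Rayleigh(sigma) is sigma: recovered within 5% at n = 10,000
  set.seed(14)
  d <- 2 * sqrt(-2 * log(runif(10000)))  # Rayleigh(2) via inverse CDF
  sm <- distance_summary(d)
  expect_lt(abs(sm$density_peak - 2) / 2, 0.05)
  expect_equal(sm$bandwidth, sd(d) * 10000^(-1 / 7))
  expect_equal(distance_summary(d, bandwidth = "scott")$bandwidth,
               sd(d) * 10000^(-1 / 5))
  expect_error(distance_summary(d, bandwidth = "nope"), "unknown bandwidth")
})

test_that("region specificity counts spots on foreground pixels", {
  pan <- gene_panel(c("in", "half", "none"))
  m <- matrix(FALSE, 10, 20); m[, 1:10] <- TRUE  # left half foreground
  msk <- raster_mask(m, pixel_size = 1)
  df <- data.frame(gene = c(rep("in", 4), rep("half", 4)),
                   x = c(1, 2, 3, 4, 2, 4, 12, 14), y = 5)
  rep_ <- region_specificity(spot_table(df, pan), msk)
  pooled <- rep_[rep_$sample == "pooled", ]
  expect_equal(pooled$fraction[pooled$gene == "in"], 1)
  expect_equal(pooled$fraction[pooled$gene == "half"], 0.5)
  expect_true(is.na(pooled$fraction[pooled$gene == "none"]))
  expect_equal(pooled$total[pooled$gene == "none"], 0L)
})

test_that("specificity is stable under mask upsampling", {
  set.seed(2)
  m <- matrix(runif(40 * 40) < 0.5, 40, 40)
  msk <- raster_mask(m, pixel_size = 1)
  up <- raster_mask(m[rep(1:40, each = 2), rep(1:40, each = 2)],
                    pixel_size = 0.5)
  pan <- gene_panel("g")
  spots <- make_spots(rep("g", 500), runif(500, 0, 40), runif(500, 0, 40),
                      panel = pan)
  f1 <- region_specificity(spots, msk)
  f2 <- region_specificity(spots, up)
  p1 <- f1$fraction[f1$sample == "pooled"]
  p2 <- f2$fraction[f2$sample == "pooled"]
  expect_equal(p1, p2)
})

test_that("a jittered region-exclusive gene keeps >= 99% in-mask specificity", {
  b <- body_scene()
  spots <- spots_for_genes(b$spots, "TpnC4")
  rep_ <- region_specificity(spots, b$region_masks$muscle, genes = "TpnC4")
  expect_gte(rep_$fraction[rep_$sample == "pooled"], 0.99)
})
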