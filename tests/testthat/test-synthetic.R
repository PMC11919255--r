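test_that("uniform genes land inside their region with Poisson-consistent counts", {
  spec <- scene_spec(extent = c(60, 60),
                     regions = list(r = list(shape = "rect", x0 = 10, y0 = 10,
                                             x1 = 50, y1 = 50)),
                     genes = list(g = list(regions = "r", pattern = "uniform",
                                           expected_spots = 1000)),
                     jitter_sd = 0)  # jitter off: containment is then exact
  out <- simulate_scene(spec, seed = 5)
  s <- out$spots
  expect_true(all(s$x >= 10 & s$x < 50 & s$y >= 10 & s$y < 50))
  band <- qpois(c(0.0005, 0.9995), 1000)  # Poisson 99.9% band
  expect_gte(nrow(s), band[1])
  expect_lte(nrow(s), band[2])
  expect_equal(nrow(s), unname(out$scene$drawn_counts["g"]))
})

test_that("nucleus-enriched sampling reproduces the Rayleigh median", {
  # positions = nucleus center + N(0, sigma^2 I), then jitter N(0, 0.14^2 I):
  # radial distance is Rayleigh(sqrt(sigma^2 + 0.14^2)), median sigma_eff*sqrt(2 ln 2)
  spec <- scene_spec(extent = c(80, 80),
                     regions = list(r = list(shape = "rect", x0 = 0, y0 = 0,
                                             x1 = 80, y1 = 80)),
                     nuclei = data.frame(x = 40, y = 40, radius = 3, region = "r"),
                     genes = list(g = list(regions = "r",
                                           pattern = "nucleus_enriched",
                                           expected_spots = 10000,
                                           params = list(sigma = 1))),
                     jitter_sd = 0.14)
  out <- simulate_scene(spec, seed = 9)
  d <- sqrt((out$spots$x - 40)^2 + (out$spots$y - 40)^2)
  sigma_eff <- sqrt(1^2 + 0.14^2)
  expected <- sigma_eff * sqrt(2 * log(2))
  expect_lt(abs(median(d) - expected) / expected, 0.05)
})

test_that("identical (spec, seed) pairs reproduce byte-identical scenes", {
  spec <- scene_spec(extent = c(50, 50),
                     regions = list(r = list(shape = "disc", cx = 25, cy = 25,
                                             r = 20)),
                     nuclei = data.frame(x = 25, y = 25, radius = 2, region = "r"),
                     genes = list(a = list(regions = "r", pattern = "uniform",
                                           expected_spots = 300),
                                  b = list(regions = "r",
                                           pattern = "nucleus_depleted",
                                           expected_spots = 300)),
                     pixel_size = 0.5)
  o1 <- simulate_scene(spec, seed = 123)
  o2 <- simulate_scene(spec, seed = 123)
  expect_identical(as.data.frame(o1$spots), as.data.frame(o2$spots))
  expect_identical(o1$nucleus_mask$mask, o2$nucleus_mask$mask)
  o3 <- simulate_scene(spec, seed = 124)
  expect_false(identical(as.data.frame(o1$spots), as.data.frame(o3$spots)))
})

test_that("per-gene spot counts equal the Poisson draws and totals add up", {
  b <- body_scene()
  counts <- table(factor(b$spots$gene, levels = names(b$scene$genes)))
  expect_equal(as.integer(counts), unname(b$scene$drawn_counts))
  expect_equal(nrow(b$spots),
               sum(b$scene$drawn_counts) + b$scene$n_background)
})

test_that("nucleus-depleted genes sit farther from nuclei than enriched ones", {
  spec <- scene_spec(extent = c(100, 100),
                     regions = list(r = list(shape = "rect", x0 = 0, y0 = 0,
                                             x1 = 100, y1 = 100)),
                     nuclei = data.frame(x = rep(seq(10, 90, 20), 5),
                                         y = rep(seq(10, 90, 20), each = 5),
                                         radius = 3, region = "r"),
                     genes = list(enr = list(regions = "r",
                                             pattern = "nucleus_enriched",
                                             expected_spots = 2500,
                                             params = list(sigma = 2)),
                                  dep = list(regions = "r",
                                             pattern = "nucleus_depleted",
                                             expected_spots = 2500,
                                             params = list(well_radius = 4,
                                                           well_factor = 0.1))),
                     pixel_size = 0.5)
  out <- simulate_scene(spec, seed = 77)
  nn <- function(g) {
    s <- out$spots[out$spots$gene == g, ]
    nx <- spec$nuclei$x; ny <- spec$nuclei$y
    vapply(seq_len(nrow(s)),
           function(i) sqrt(min((s$x[i] - nx)^2 + (s$y[i] - ny)^2)), numeric(1))
  }
  expect_gte(sum(out$spots$gene == "enr"), 2000)
  expect_lt(median(nn("enr")), median(nn("dep")))
})

test_that("scene specs are validated", {
  r <- list(r = list(shape = "rect", x0 = 0, y0 = 0, x1 = 10, y1 = 10))
  expect_error(scene_spec(c(5, 5), r, genes = list()), "exceeds the scene extent")
  expect_error(
    scene_spec(c(20, 20), r,
               genes = list(g = list(regions = "r",
                                     pattern = "nucleus_enriched",
                                     expected_spots = 10))),
    "needs nuclei")
  expect_error(
    scene_spec(c(20, 20), r,
               genes = list(g = list(regions = "r", pattern = "striped",
                                     expected_spots = 10,
                                     params = list(period = -1)))),
    "period")
  expect_error(
    scene_spec(c(20, 20), r,
               genes = list(g = list(regions = "r", pattern = "boundary_apical",
                                     expected_spots = 10))),
    "annulus")
  expect_error(
    scene_spec(c(20, 20), r,
               nuclei = data.frame(x = 15, y = 15, radius = 1, region = "r"),
               genes = list()),
    "within their region")
})

test_that("the canned body scene has the promised structure", {
  b <- body_scene()
  spec <- b$scene
  # every region has at least one exclusive marker gene
  by_region <- split(names(b$gene_regions), b$gene_regions)
  expect_setequal(names(by_region), names(spec$regions))
  multi <- vapply(spec$genes, function(g) length(g$regions) > 1, logical(1))
  expect_false(any(multi))
  # the two striped genes are in antiphase: offset of half a period
  ph <- vapply(c("Act88F", "Mhc"),
               function(g) spec$genes[[g]]$params$phase %||% 0, numeric(1))
  per <- spec$genes$Act88F$params$period
  expect_equal(abs(unname(diff(ph))), pi)  # phase offset pi ...
  expect_equal(per * abs(unname(diff(ph))) / (2 * pi), per / 2)  # = period/2 in u
  # muscle-exclusive spots leak out of the region mask by at most 1%
  msk <- b$region_masks$muscle
  for (g in c("TpnC4", "Act88F")) {
    s <- b$spots[b$spots$gene == g, ]
    expect_gte(mean(mask_contains(msk, s$x, s$y)), 0.99)
  }
})

test_that("scene bundles write to disk with ground truth", {
  sc <- three_group_scene(seed = 3, spots_per_gene = 30)
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  expect_true(file.exists(file.path(dir, "spots.tsv")))
  truth <- yaml::read_yaml(file.path(dir, "ground_truth.yaml"))
  expect_equal(truth$seed, 3)
  expect_equal(sum(unlist(truth$drawn_counts)), nrow(sc$spots))
  back <- read_mask(file.path(dir, "nuclei.pgm"))
  expect_identical(back$mask, sc$nucleus_mask$mask)
})
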