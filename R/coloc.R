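#' Disk-overlap colocalization between mRNA species
#'
#' Every molecule of a species is replaced by a disk of fixed diameter
#' (default 4 um) centered on its position; overlapping disks of the same
#' species are merged so each species contributes a single union surface.
#' For a pair of species the overlap of the two union surfaces defines the
#' asymmetric proximities
#' \deqn{Proximity_{A in B} = Overlap_{A,B} / Surface_B, \quad
#'       Proximity_{B in A} = Overlap_{A,B} / Surface_A}
#' and the symmetric distance
#' \deqn{D_{A,B} = 2 - (Proximity_{A in B} + Proximity_{B in A})}
#' so perfectly overlapping species get distance 0 and species with no
#' overlap get distance 2.
#'
#' Areas are computed on a raster of square cells (default 0.1 um): a cell
#' counts as covered when its center lies within one disk radius of any spot.
#' Rasters of different species share one global cell lattice (cell `k` spans
#' `[k*res, (k+1)*res)`), so intersections are well defined.
#'
#' @name coloc
NULL

# cell-index ranges covering [lo, hi] on the global lattice
.cell_range <- function(lo, hi, res) {
  lo_i <- floor(lo / res)
  hi_i <- floor(hi / res)
  seq.int(lo_i, hi_i)
}

# per-cell coverage weights (rows = y cells, cols = x cells) of the disk
# union over the given cell index vectors. Boundary cells get an antialiased
# weight in [0, 1] from the signed distance of the cell center to the disk
# edge (linear ramp one cell wide); interior cells are exactly 1. This kills
# the lattice-count (Gauss-circle) fluctuation of a hard center-in test and
# makes area estimates converge smoothly with resolution.
.disk_cover <- function(x, y, r, res, ix, iy) {
  m <- matrix(0, nrow = length(iy), ncol = length(ix))
  cx <- (ix + 0.5) * res
  cy <- (iy + 0.5) * res
  x0 <- ix[1]; y0 <- iy[1]
  nx <- length(ix); ny <- length(iy)
  reach <- r + res
  for (s in seq_along(x)) {
    jlo <- max(1L, floor((x[s] - reach) / res) - x0 + 1L)
    jhi <- min(nx, floor((x[s] + reach) / res) - x0 + 1L)
    ilo <- max(1L, floor((y[s] - reach) / res) - y0 + 1L)
    ihi <- min(ny, floor((y[s] + reach) / res) - y0 + 1L)
    if (jlo > jhi || ilo > ihi) next
    dx2 <- (cx[jlo:jhi] - x[s])^2
    dy2 <- (cy[ilo:ihi] - y[s])^2
    d <- sqrt(outer(dy2, dx2, "+"))
    w <- pmin(1, pmax(0, (r - d) / res + 0.5))
    m[ilo:ihi, jlo:jhi] <- pmax(m[ilo:ihi, jlo:jhi], w)
  }
  m
}

.spot_xy <- function(spots) {
  if (inherits(spots, "spot_table")) cbind(spots$x, spots$y)
  else as.matrix(spots)[, 1:2, drop = FALSE]
}

#' Union surface of one species' merged disks
#'
#' @param spots a `spot_table` (single gene) or a 2-column matrix/data.frame
#'   of x, y coordinates in um.
#' @param diameter disk diameter, um (default 4).
#' @param resolution raster cell size, um (default 0.1).
#' @return area in um^2.
#' @export
disk_union_surface <- function(spots, diameter = 4, resolution = 0.1) {
  xy <- .spot_xy(spots)
  if (nrow(xy) == 0L)
    stop("surface undefined for an empty spot set")
  .assert_scalar_num(diameter, "diameter", positive = TRUE)
  .assert_scalar_num(resolution, "resolution", positive = TRUE)
  r <- diameter / 2
  ix <- .cell_range(min(xy[, 1]) - r, max(xy[, 1]) + r, resolution)
  iy <- .cell_range(min(xy[, 2]) - r, max(xy[, 2]) + r, resolution)
  sum(.disk_cover(xy[, 1], xy[, 2], r, resolution, ix, iy)) * resolution^2
}

#' Pairwise proximity between two species
#'
#' @param spots_a,spots_b spot coordinates as in [disk_union_surface()].
#' @inheritParams disk_union_surface
#' @return list with `prox_a_in_b` (= overlap / surface_b), `prox_b_in_a`
#'   (= overlap / surface_a), `overlap`, `surface_a`, `surface_b` (um^2).
#' @export
pairwise_proximity <- function(spots_a, spots_b, diameter = 4,
                               resolution = 0.1) {
  a <- .spot_xy(spots_a); b <- .spot_xy(spots_b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("proximity undefined when either species has no spots")
  r <- diameter / 2
  surface_a <- disk_union_surface(a, diameter, resolution)
  surface_b <- disk_union_surface(b, diameter, resolution)
  # overlap only possible inside the intersection of the padded bounding boxes
  lox <- max(min(a[, 1]), min(b[, 1])) - r
  hix <- min(max(a[, 1]), max(b[, 1])) + r
  loy <- max(min(a[, 2]), min(b[, 2])) - r
  hiy <- min(max(a[, 2]), max(b[, 2])) + r
  overlap <- 0
  if (lox <= hix && loy <= hiy) {
    ix <- .cell_range(lox, hix, resolution)
    iy <- .cell_range(loy, hiy, resolution)
    ca <- .disk_cover(a[, 1], a[, 2], r, resolution, ix, iy)
    cb <- .disk_cover(b[, 1], b[, 2], r, resolution, ix, iy)
    overlap <- sum(pmin(ca, cb)) * resolution^2
  }
  list(prox_a_in_b = overlap / surface_b,
       prox_b_in_a = overlap / surface_a,
       overlap = overlap, surface_a = surface_a, surface_b = surface_b)
}

#' Gene-gene colocalization distance matrix
#'
#' Computes union surfaces for every panel gene with at least one spot,
#' pairwise overlaps and proximities, and the symmetric distance matrix
#' `D = 2 - (prox_a_in_b + prox_b_in_a)` with zero diagonal. Genes without
#' spots are excluded and reported via a message and the `excluded` field.
#'
#' @param spots a `spot_table` (typically one sample; pool upstream if wanted).
#' @param config an [analysis_config()] supplying `disk_diameter` and
#'   `coloc_resolution`.
#' @param genes optional subset of panel genes.
#' @return a `coloc_result`: list with `distance` (matrix in \[0, 2\]),
#'   `proximity` (`P[a, b]` = prox of a in b), `overlap`, `surfaces`,
#'   `diameter`, `resolution`, `excluded`.
#' @export
coloc_distance_matrix <- function(spots, config = analysis_config(),
                                  genes = NULL) {
  stopifnot(inherits(spots, "spot_table"))
  genes <- genes %||% unclass(spot_panel(spots))
  counts <- table(factor(spots$gene, levels = genes))
  excluded <- names(counts)[counts == 0]
  if (length(excluded))
    message("coloc_distance_matrix: excluding ", length(excluded),
            " gene(s) with no spots: ", paste(excluded, collapse = ", "))
  genes <- setdiff(genes, excluded)
  if (length(genes) < 2L)
    stop("need at least two genes with spots (have ", length(genes), ")")
  d <- config$disk_diameter
  res <- config$coloc_resolution
  xy <- lapply(genes, function(g) {
    s <- spots[spots$gene == g, , drop = FALSE]
    cbind(s$x, s$y)
  })
  names(xy) <- genes
  surfaces <- vapply(xy, disk_union_surface, numeric(1),
                     diameter = d, resolution = res)
  n <- length(genes)
  P <- matrix(0, n, n, dimnames = list(genes, genes))
  O <- matrix(0, n, n, dimnames = list(genes, genes))
  diag(P) <- 1
  diag(O) <- surfaces
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        pr <- pairwise_proximity(xy[[i]], xy[[j]], diameter = d,
                                 resolution = res)
        P[i, j] <- pr$prox_a_in_b
        P[j, i] <- pr$prox_b_in_a
        O[i, j] <- O[j, i] <- pr$overlap
      }
    }
  }
  D <- 2 - (P + t(P))
  diag(D) <- 0
  D[D < 0] <- 0   # raster rounding guard; exact bounds hold analytically
  D[D > 2] <- 2
  structure(list(distance = D, proximity = P, overlap = O,
                 surfaces = surfaces, diameter = d, resolution = res,
                 excluded = excluded),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d genes, disk %g um, raster %g um\n",
              nrow(x$distance), x$diameter, x$resolution))
  invisible(x)
}

#' Ward clustering of genes from a colocalization distance matrix
#'
#' Agglomerative clustering with Ward linkage applied to the distance matrix
#' as-is (no embedding); clusters extracted by count `k` or dendrogram height
#' `h` (exactly one must be given).
#'
#' @param result a `coloc_result` (or a symmetric distance matrix).
#' @param k number of clusters, or `NULL`.
#' @param h cut height, or `NULL`.
#' @return list with `labels` (named integer vector), `hclust` (the tree) and
#'   `k`.
#' @export
ward_gene_clustering <- function(result, k = NULL, h = NULL) {
  D <- if (inherits(result, "coloc_result")) result$distance else as.matrix(result)
  if (is.null(k) == is.null(h))
    stop("specify exactly one of k (cluster count) or h (cut height)")
  if (!is.null(k) && k > nrow(D))
    stop("k = ", k, " exceeds the number of genes (", nrow(D), ")")
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  labels <- stats::cutree(hc, k = k, h = h)
  list(labels = labels, hclust = hc, k = length(unique(labels)))
}

#' Export a gene dendrogram as Newick
#'
#' @param clustering result of [ward_gene_clustering()] (or an `hclust`).
#' @param path optional file; if `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
dendrogram_newick <- function(clustering, path = NULL) {
  hc <- if (inherits(clustering, "hclust")) clustering else clustering$hclust
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
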