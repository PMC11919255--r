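#' Binary morphology and tissue-mask construction
#'
#' The tissue mask is derived from the spots of one abundant marker gene:
#' spots are rendered as single foreground pixels, then a Gaussian blur
#' (ksize 5, sigma 1, re-binarized at > 0), two erosions (5x5 then 4x4) to
#' remove sparse signal, three 50x50 dilations to close the tissue, and a
#' final Gaussian blur (5, 1, re-binarized) are applied, in that order.
#'
#' Kernel windows use offsets `-floor(k/2) .. k - 1 - floor(k/2)` per axis
#' (the default-anchor convention of common image toolkits; asymmetric for
#' even sizes). Out-of-image pixels count as background for both erosion and
#' dilation.
#'
#' @name morphology
NULL

# summed-area table: S[i+1, j+1] = sum of m[1:i, 1:j]
.sat <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1L, nc + 1L)
  if (nr && nc) {
    cs <- apply(m * 1, 2L, cumsum)
    cs <- matrix(cs, nrow = nr)
    S[-1L, -1L] <- t(apply(cs, 1L, cumsum))
  }
  S
}

# sum of m over the window [i+lo_r, i+hi_r] x [j+lo_c, j+hi_c] per pixel,
# zero-padded outside the image
.box_sum <- function(m, kh, kw) {
  nr <- nrow(m); nc <- ncol(m)
  lo_r <- -(kh %/% 2L); hi_r <- kh - 1L - (kh %/% 2L)
  lo_c <- -(kw %/% 2L); hi_c <- kw - 1L - (kw %/% 2L)
  S <- .sat(m)
  r1 <- pmin(pmax(seq_len(nr) + hi_r, 0L), nr)
  r0 <- pmin(pmax(seq_len(nr) + lo_r - 1L, 0L), nr)
  c1 <- pmin(pmax(seq_len(nc) + hi_c, 0L), nc)
  c0 <- pmin(pmax(seq_len(nc) + lo_c - 1L, 0L), nc)
  S[r1 + 1L, c1 + 1L] - S[r0 + 1L, c1 + 1L] -
    S[r1 + 1L, c0 + 1L] + S[r0 + 1L, c0 + 1L]
}

#' @rdname morphology
#' @param m logical matrix.
#' @param kh,kw kernel height/width (solid rectangle).
#' @return logical matrix of the same shape.
#' @export
erode_rect <- function(m, kh, kw) .box_sum(m, kh, kw) == kh * kw

#' @rdname morphology
#' @export
dilate_rect <- function(m, kh, kw) .box_sum(m, kh, kw) > 0

# separable Gaussian convolution, zero padding; returns numeric matrix
.gaussian_blur <- function(m, ksize = 5L, sigma = 1) {
  half <- (ksize - 1L) %/% 2L
  g <- stats::dnorm(seq.int(-half, half), sd = sigma)
  g <- g / sum(g)
  out <- m * 1
  shift_rows <- function(x, o) {
    nr <- nrow(x)
    z <- matrix(0, nr, ncol(x))
    if (o >= 0 && o < nr) z[seq_len(nr - o) + o, ] <- x[seq_len(nr - o), ]
    if (o < 0 && -o < nr) z[seq_len(nr + o), ] <- x[seq_len(nr + o) - o, ]
    z
  }
  acc <- matrix(0, nrow(m), ncol(m))
  for (o in seq_along(g)) acc <- acc + g[o] * shift_rows(out, o - half - 1L)
  out <- acc
  acc <- matrix(0, nrow(m), ncol(m))
  for (o in seq_along(g)) acc <- acc + g[o] * t(shift_rows(t(out), o - half - 1L))
  acc
}

#' Build a tissue mask from marker-gene spots
#'
#' Applies the morphology recipe described in [morphology] to a raster of the
#' marker's spot positions. The raster covers the spot bounding box padded by
#' the maximum structuring reach (or the geometry of `template` if given, so
#' masks from different markers align).
#'
#' @param marker_spots a `spot_table` (typically one gene's spots).
#' @param config an [analysis_config()]; uses `pixel_size` and `morphology`.
#' @param template optional `raster_mask` whose extent/origin/scale to reuse.
#' @return a binary `raster_mask`. Empty input yields an empty mask with a
#'   warning.
#' @export
build_tissue_mask <- function(marker_spots, config = analysis_config(),
                              template = NULL) {
  stopifnot(inherits(marker_spots, "spot_table"))
  ps <- config$pixel_size
  mo <- config$morphology
  pad_px <- mo$dilate$times * max(mo$dilate$ksize) %/% 2L + 8L
  if (!is.null(template)) {
    base <- raster_mask(matrix(FALSE, nrow(template$mask), ncol(template$mask)),
                        pixel_size = template$pixel_size,
                        origin = template$origin)
  } else if (nrow(marker_spots) == 0L) {
    warning("no marker spots: returning an empty 1x1 mask")
    return(raster_mask(matrix(FALSE, 1, 1), pixel_size = ps))
  } else {
    ox <- floor(min(marker_spots$x) / ps - pad_px) * ps
    oy <- floor(min(marker_spots$y) / ps - pad_px) * ps
    nc <- ceiling((max(marker_spots$x) - ox) / ps) + pad_px
    nr <- ceiling((max(marker_spots$y) - oy) / ps) + pad_px
    base <- raster_mask(matrix(FALSE, nr, nc), pixel_size = ps,
                        origin = c(ox, oy))
  }
  m <- base$mask
  if (nrow(marker_spots)) {
    px <- world_to_pixel(base, marker_spots$x, marker_spots$y)
    ok <- px$i >= 1 & px$i <= nrow(m) & px$j >= 1 & px$j <= ncol(m)
    m[cbind(px$i[ok], px$j[ok])] <- TRUE
  }
  m <- .gaussian_blur(m, mo$blur1[["ksize"]], mo$blur1[["sigma"]]) > 0
  for (k in mo$erode) m <- erode_rect(m, k[1], k[2])
  for (t in seq_len(mo$dilate$times))
    m <- dilate_rect(m, mo$dilate$ksize[1], mo$dilate$ksize[2])
  m <- .gaussian_blur(m, mo$blur2[["ksize"]], mo$blur2[["sigma"]]) > 0
  if (!any(m) && nrow(marker_spots))
    warning("tissue mask is empty after morphology (sparse marker signal)")
  raster_mask(m, pixel_size = base$pixel_size, origin = base$origin)
}

# exact nearest-foreground-pixel-center distances, chunked all-pairs minimum
.nn_dist <- function(sx, sy, px, py, chunk = 128L) {
  out <- numeric(length(sx))
  n <- length(sx)
  i <- 1L
  while (i <= n) {
    id <- i:min(i + chunk - 1L, n)
    d2 <- outer(sx[id], px, "-")^2 + outer(sy[id], py, "-")^2
    out[id] <- sqrt(matrixStats::rowMins(d2))
    i <- i + chunk
  }
  out
}

#' Per-gene nearest-nucleus distance profiles
#'
#' For every spot, the Euclidean distance (um) to the nearest foreground
#' pixel center of the nucleus mask — by contract equal to the exhaustive
#' all-pairs minimum. Spots inside nuclei naturally get distances at most
#' half a pixel diagonal. If a tissue mask is given, only spots on its
#' foreground are kept before profiling. Genes with fewer than
#' `min_gene_spots` retained spots are excluded (reported in the result's
#' `excluded` attribute).
#'
#' @param spots a `spot_table` (all samples pooled).
#' @param nucleus_mask a nonempty `raster_mask` of segmented nuclei.
#' @param tissue_mask optional `raster_mask` restricting the analysis.
#' @param min_gene_spots minimum pooled spots per reported gene (default 100).
#' @return named list of `distance_profile` objects (`gene`, `distances`,
#'   `n`), with attribute `excluded` naming genes below the spot minimum.
#' @export
nearest_nucleus_distances <- function(spots, nucleus_mask, tissue_mask = NULL,
                                      min_gene_spots = 100L) {
  stopifnot(inherits(spots, "spot_table"), inherits(nucleus_mask, "raster_mask"))
  if (!any(nucleus_mask$mask)) stop("nucleus mask has no foreground pixels")
  if (!is.null(tissue_mask)) {
    keep <- mask_contains(tissue_mask, spots$x, spots$y)
    spots <- spots[keep, , drop = FALSE]
  }
  fg <- foreground_coords(nucleus_mask)
  genes <- unique(spots$gene)
  profiles <- list()
  excluded <- character()
  for (g in genes) {
    sel <- spots$gene == g
    n <- sum(sel)
    if (n < min_gene_spots) {
      excluded <- c(excluded, g)
      next
    }
    d <- .nn_dist(spots$x[sel], spots$y[sel], fg$x, fg$y)
    profiles[[g]] <- structure(list(gene = g, distances = d, n = n),
                               class = "distance_profile")
  }
  attr(profiles, "excluded") <- excluded
  profiles
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile> %s: n = %d, median = %.3g um\n",
              x$gene, x$n, stats::median(x$distances)))
  invisible(x)
}

#' Median and density-peak summary of a distance profile
#'
#' The median is the empirical 50th percentile; the density peak is the
#' argmax of a Gaussian kernel density estimate on a regular grid. Bandwidth
#' rules: `"scott-mode"` (default), `sd(x) * n^(-1/7)` — Scott's factor with
#' the mode-optimal rate exponent, since the reported quantity is the argmax
#' of the density, for which the classical `n^(-1/5)` density-optimal rate
#' undersmooths; `"scott"`, `sd(x) * n^(-1/5)`; or a numeric bandwidth in um.
#'
#' @param profile a `distance_profile` (or numeric vector of distances).
#' @param bandwidth `"scott-mode"`, `"scott"`, or a numeric bandwidth (um).
#' @param n_grid density evaluation grid size.
#' @return list with `median`, `density_peak`, `bandwidth` (um).
#' @export
distance_summary <- function(profile, bandwidth = "scott-mode",
                             n_grid = 512L) {
  d <- if (inherits(profile, "distance_profile")) profile$distances
       else as.numeric(profile)
  if (length(d) < 2L) stop("need at least 2 distances to summarize")
  if (is.character(bandwidth)) {
    rate <- switch(bandwidth, `scott-mode` = -1 / 7, scott = -1 / 5,
                   stop("unknown bandwidth rule: ", bandwidth))
    bw <- stats::sd(d) * length(d)^rate
    if (bw == 0) bw <- 1e-6  # degenerate: all distances equal
  } else {
    bw <- .assert_scalar_num(bandwidth, "bandwidth", positive = TRUE)
  }
  dens <- stats::density(d, bw = bw, n = n_grid)
  list(median = stats::median(d),
       density_peak = dens$x[which.max(dens$y)],
       bandwidth = bw)
}

#' Marker specificity: fraction of a gene's spots inside a region
#'
#' For each panel gene, the number of spots whose coordinates fall on
#' foreground pixels of `region_mask`, per sample and pooled. Genes with zero
#' spots are reported with `NA` fraction (undefined, not 0).
#'
#' @param spots a `spot_table`.
#' @param region_mask a `raster_mask` of the segmented region.
#' @param genes optional subset of panel genes (default: whole panel).
#' @return data.frame `gene`, `sample` (`"pooled"` rows included), `inside`,
#'   `total`, `fraction`.
#' @export
region_specificity <- function(spots, region_mask, genes = NULL) {
  stopifnot(inherits(spots, "spot_table"), inherits(region_mask, "raster_mask"))
  genes <- genes %||% unclass(spot_panel(spots))
  inside <- mask_contains(region_mask, spots$x, spots$y)
  samples <- sort(unique(spots$sample))
  rows <- list()
  for (g in genes) {
    sel <- spots$gene == g
    for (s in c(samples, "pooled")) {
      pick <- sel & (s == "pooled" | spots$sample == s)
      tot <- sum(pick)
      ins <- sum(inside & pick)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, sample = s, inside = ins, total = tot,
        fraction = if (tot > 0) ins / tot else NA_real_)
    }
  }
  do.call(rbind, rows)
}
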