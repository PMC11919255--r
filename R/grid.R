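#' Pseudo-bulk count grid
#'
#' Squares-by-genes matrix obtained by rasterizing a spot table into an axis
#' aligned grid. Internal constructor; users obtain grids via
#' [rasterize_spots()].
#'
#' @format A `count_grid` is a list with elements:
#' \describe{
#'   \item{counts}{sparse `dgCMatrix`, squares x genes. Raw integer counts, or
#'     log-normalized values after [normalize_grid()].}
#'   \item{squares}{data.frame: `square_id`, `sample`, `ix`, `iy` (integer bin
#'     indices), `cx`, `cy` (square centers, um), `total` (raw total counts).}
#'   \item{side}{square side length, um.}
#'   \item{normalized}{logical state flag.}
#'   \item{panel}{the `gene_panel` (column order).}
#' }
#' @name count_grid
NULL

.new_count_grid <- function(counts, squares, side, normalized, panel) {
  structure(list(counts = counts, squares = squares, side = side,
                 normalized = normalized, panel = panel),
            class = "count_grid")
}

#' @export
print.count_grid <- function(x, ...) {
  cat(sprintf("<count_grid> %d squares x %d genes, side %g um, %s\n",
              nrow(x$counts), ncol(x$counts), x$side,
              if (x$normalized) "log-normalized" else "raw counts"))
  invisible(x)
}

#' Rasterize a spot table into a square grid
#'
#' Each spot is assigned to exactly one square by `floor(coordinate / side)`
#' per axis, independently per sample (bins are half-open,
#' `[k*side, (k+1)*side)`, with the binning origin fixed at world (0, 0) for
#' every sample; negative coordinates floor toward -Inf). Counts are conserved:
#' the matrix grand total equals the number of spots. With the default
#' configuration the side is 36 px x 0.138 um/px = 4.968 um.
#'
#' Only squares containing at least one spot are materialized; all panel genes
#' appear as columns, including zero-count ones.
#'
#' @param spots a `spot_table`.
#' @param config an [analysis_config()] (used for `bin_pixels * pixel_size`).
#' @param side override the square side length (um).
#' @return a [count_grid].
#' @export
rasterize_spots <- function(spots, config = analysis_config(), side = NULL) {
  stopifnot(inherits(spots, "spot_table"))
  side <- side %||% grid_side(config)
  .assert_scalar_num(side, "side", positive = TRUE)
  panel <- spot_panel(spots)
  genes <- unclass(panel)
  if (nrow(spots) == 0L) {
    counts <- Matrix::Matrix(0, nrow = 0, ncol = length(genes), sparse = TRUE,
                             dimnames = list(NULL, genes))
    squares <- data.frame(square_id = character(), sample = character(),
                          ix = integer(), iy = integer(),
                          cx = numeric(), cy = numeric(), total = numeric())
    return(.new_count_grid(methods::as(counts, "CsparseMatrix"), squares,
                           side, FALSE, panel))
  }
  dt <- data.table::data.table(gene = spots$gene, sample = spots$sample,
                               ix = as.integer(floor(spots$x / side)),
                               iy = as.integer(floor(spots$y / side)))
  tal <- dt[, .N, by = c("sample", "ix", "iy", "gene")]
  sq <- unique(tal[, c("sample", "ix", "iy")])
  data.table::setorderv(sq, c("sample", "iy", "ix"))
  sq[, `:=`(square_id = paste(sample, ix, iy, sep = "_"),
            cx = (ix + 0.5) * side, cy = (iy + 0.5) * side)]
  row_of <- stats::setNames(seq_len(nrow(sq)), sq$square_id)
  col_of <- stats::setNames(seq_along(genes), genes)
  counts <- Matrix::sparseMatrix(
    i = row_of[paste(tal$sample, tal$ix, tal$iy, sep = "_")],
    j = col_of[tal$gene], x = tal$N,
    dims = c(nrow(sq), length(genes)),
    dimnames = list(sq$square_id, genes))
  squares <- as.data.frame(sq[, c("square_id", "sample", "ix", "iy", "cx", "cy")])
  squares$total <- Matrix::rowSums(counts)
  .new_count_grid(counts, squares, side, FALSE, panel)
}

#' Filter grid squares by total count
#'
#' Retains squares whose raw total count is strictly greater than
#' `min_square_counts` (default 3, i.e. "more than three counts"). Square
#' order is preserved.
#'
#' @param grid an unnormalized [count_grid].
#' @param min_square_counts strict lower bound.
#' @return the filtered `count_grid`.
#' @export
filter_squares <- function(grid, min_square_counts = 3L) {
  stopifnot(inherits(grid, "count_grid"))
  if (grid$normalized)
    stop("filter_squares() expects raw counts; grid is already normalized")
  keep <- grid$squares$total > min_square_counts
  .new_count_grid(grid$counts[keep, , drop = FALSE],
                  {s <- grid$squares[keep, , drop = FALSE]; rownames(s) <- NULL; s},
                  grid$side, FALSE, grid$panel)
}

#' Size-factor log normalization of a grid
#'
#' Per square: `value = log(1 + size_factor * count / square_total)` (natural
#' log). Equivalent to scaling each square to a fixed total of `size_factor`
#' followed by log1p. Normalizing twice is a state error. Squares with zero
#' total (possible only on unfiltered grids) keep all-zero values.
#'
#' @param grid a (typically filtered) raw [count_grid].
#' @param size_factor target total per square (default 10,000).
#' @return the normalized `count_grid` (`normalized = TRUE`).
#' @export
normalize_grid <- function(grid, size_factor = 10000) {
  stopifnot(inherits(grid, "count_grid"))
  .assert_scalar_num(size_factor, "size_factor", positive = TRUE)
  if (grid$normalized)
    stop("grid is already normalized (refusing to normalize twice)")
  counts <- grid$counts
  tot <- grid$squares$total
  scale <- ifelse(tot > 0, size_factor / tot, 0)
  norm <- methods::as(Matrix::Diagonal(x = scale) %*% counts, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  .new_count_grid(norm, grid$squares, grid$side, TRUE, grid$panel)
}

#' Dense matrix view of a grid
#' @param grid a [count_grid].
#' @return base matrix (squares x genes) with dimnames.
#' @export
grid_matrix <- function(grid) as.matrix(grid$counts)
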