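#' Write a count grid to disk
#'
#' Two formats:
#' \describe{
#'   \item{`"mtx"`}{Matrix Market triplets (`matrix.mtx`) plus `genes.tsv`,
#'     `squares.tsv` and `grid.yaml` (side length, normalization flag) in a
#'     directory. Integer grids use `Matrix::writeMM`; real-valued (normalized)
#'     grids are written with 17 significant digits so the round trip is exact
#'     to the double representation.}
#'   \item{`"tsv"`}{a dense `matrix.tsv` (squares x genes, square_id first
#'     column) with the same sidecars.}
#' }
#' Counts, square centroids and gene order round-trip losslessly through
#' [read_count_matrix()].
#'
#' @param grid a [count_grid].
#' @param dir output directory (created if needed).
#' @param format `"mtx"` or `"tsv"`.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(grid, dir, format = c("mtx", "tsv")) {
  stopifnot(inherits(grid, "count_grid"))
  format <- match.arg(format)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  sq <- grid$squares
  numcols <- vapply(sq, is.numeric, logical(1))
  sq_out <- sq
  sq_out[numcols] <- lapply(sq_out[numcols],
                            function(x) formatC(x, digits = 17, format = "g"))
  data.table::fwrite(sq_out, file.path(dir, "squares.tsv"), sep = "\t",
                     quote = FALSE)
  writeLines(colnames(grid$counts), file.path(dir, "genes.tsv"))
  yaml::write_yaml(list(side = grid$side, normalized = grid$normalized,
                        format = format),
                   file.path(dir, "grid.yaml"))
  if (format == "mtx") {
    if (grid$normalized) {
      .write_mm_real(grid$counts, file.path(dir, "matrix.mtx"))
    } else {
      Matrix::writeMM(grid$counts, file.path(dir, "matrix.mtx"))
    }
  } else {
    m <- as.matrix(grid$counts)
    df <- data.frame(square_id = rownames(m) %||% sq$square_id,
                     apply(m, 2, function(x) formatC(x, digits = 17, format = "g")),
                     check.names = FALSE)
    if (nrow(m) == 0L)
      df <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = ncol(m) + 1)),
                            c("square_id", colnames(m)))
    data.table::fwrite(df, file.path(dir, "matrix.tsv"), sep = "\t",
                       quote = FALSE)
  }
  invisible(dir)
}

# MatrixMarket coordinate/real writer at full double precision
.write_mm_real <- function(m, path) {
  tm <- methods::as(methods::as(m, "TsparseMatrix"), "generalMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate real general", con)
  writeLines(paste(nrow(m), ncol(m), length(tm@x)), con)
  if (length(tm@x))
    writeLines(paste(tm@i + 1L, tm@j + 1L,
                     formatC(tm@x, digits = 17, format = "g")), con)
  invisible(path)
}

#' Read a count grid written by [write_count_matrix()]
#'
#' @param dir directory containing the export.
#' @return a [count_grid].
#' @export
read_count_matrix <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "grid.yaml"))
  genes <- if (file.size(file.path(dir, "genes.tsv")) > 0)
    readLines(file.path(dir, "genes.tsv")) else character()
  squares <- data.table::fread(file.path(dir, "squares.tsv"),
                               sep = "\t", data.table = FALSE,
                               colClasses = list(character = c("square_id", "sample")))
  if (meta$format == "mtx") {
    counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
    # writeMM encodes all-ones matrices as "pattern"; restore numeric values
    counts <- methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix")
    dimnames(counts) <- list(squares$square_id, genes)
  } else {
    df <- data.table::fread(file.path(dir, "matrix.tsv"), sep = "\t",
                            data.table = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    counts <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    dimnames(counts) <- list(squares$square_id, genes)
  }
  .new_count_grid(counts, squares, meta$side, meta$normalized,
                  gene_panel(genes))
}
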