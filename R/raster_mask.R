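#' Binary raster mask with world coordinates
#'
#' A logical matrix anchored in the world (micrometre) frame. Pixel `(i, j)`
#' (1-based row/column) covers the half-open square
#' `[origin_x + (j-1)*s, origin_x + j*s) x [origin_y + (i-1)*s, origin_y + i*s)`
#' where `s` is `pixel_size`; its center sits at `origin + (index - 0.5) * s`.
#' Row index grows with y (image convention: y increases downward).
#'
#' @param mask matrix; any nonzero/`TRUE` entry is foreground.
#' @param pixel_size micrometres per pixel (> 0); default 0.138.
#' @param origin numeric length-2, world coordinates (um) of the top-left
#'   corner of pixel (1, 1).
#' @return a `raster_mask` object.
#' @export
raster_mask <- function(mask, pixel_size = 0.138, origin = c(0, 0)) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  .assert_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  origin <- as.numeric(origin)
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("origin must be two finite numbers (x, y) in um")
  m <- if (is.logical(mask)) mask else mask != 0
  m[is.na(m)] <- FALSE
  structure(list(mask = m, pixel_size = pixel_size, origin = origin),
            class = "raster_mask")
}

#' @export
print.raster_mask <- function(x, ...) {
  cat(sprintf("<raster_mask> %d x %d px @ %g um/px, origin (%g, %g) um, %d foreground px\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size,
              x$origin[1], x$origin[2], sum(x$mask)))
  invisible(x)
}

#' World to pixel index mapping
#'
#' @param mask a `raster_mask`.
#' @param x,y world coordinates in um.
#' @return data.frame with 1-based `i` (row) and `j` (column); indices may
#'   fall outside the raster extent.
#' @export
world_to_pixel <- function(mask, x, y) {
  s <- mask$pixel_size
  data.frame(i = floor((y - mask$origin[2]) / s) + 1L,
             j = floor((x - mask$origin[1]) / s) + 1L)
}

#' Pixel index to world coordinates (pixel centers)
#'
#' @inheritParams world_to_pixel
#' @param i,j 1-based row/column indices.
#' @return data.frame with `x`, `y` um of the pixel centers.
#' @export
pixel_to_world <- function(mask, i, j) {
  s <- mask$pixel_size
  data.frame(x = mask$origin[1] + (j - 0.5) * s,
             y = mask$origin[2] + (i - 0.5) * s)
}

#' Test whether world points fall on foreground pixels
#'
#' Points outside the raster extent are `FALSE`.
#'
#' @inheritParams world_to_pixel
#' @return logical vector.
#' @export
mask_contains <- function(mask, x, y) {
  px <- world_to_pixel(mask, x, y)
  ok <- px$i >= 1L & px$i <= nrow(mask$mask) & px$j >= 1L & px$j <= ncol(mask$mask)
  out <- logical(length(x))
  out[ok] <- mask$mask[cbind(px$i[ok], px$j[ok])]
  out
}

#' Foreground pixel centers in world coordinates
#'
#' @param mask a `raster_mask`.
#' @return data.frame with `x`, `y` (um) of every foreground pixel center.
#' @export
foreground_coords <- function(mask) {
  idx <- which(mask$mask, arr.ind = TRUE)
  pixel_to_world(mask, idx[, 1], idx[, 2])
}

#' Read a binary mask image
#'
#' Supports single-channel PNG and plain-text PGM/PBM (magic `P1`/`P2`). Any
#' nonzero value is foreground. If `pixel_size`/`origin` are not given, a YAML
#' sidecar `<path>.yaml` with fields `pixel_size` and `origin` is consulted;
#' otherwise defaults (0.138 um/px, origin 0,0) apply.
#'
#' @param path image file.
#' @param pixel_size,origin see [raster_mask()]; `NULL` = sidecar/defaults.
#' @param reduce for multi-channel PNG: `NULL` (error), `"any"` (foreground if
#'   any channel nonzero) or `"first"`.
#' @return a `raster_mask`.
#' @export
read_mask <- function(path, pixel_size = NULL, origin = NULL, reduce = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".yaml")
  if ((is.null(pixel_size) || is.null(origin)) && file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    pixel_size <- pixel_size %||% meta$pixel_size
    origin <- origin %||% meta$origin
  }
  pixel_size <- pixel_size %||% 0.138
  origin <- origin %||% c(0, 0)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      if (is.null(reduce))
        stop("multi-channel image: supply reduce = \"any\" or \"first\"")
      img <- switch(reduce,
                    any = apply(img != 0, c(1, 2), any),
                    first = img[, , 1],
                    stop("unknown reduce rule: ", reduce))
    }
    m <- img != 0
  } else if (ext %in% c("pgm", "pbm")) {
    m <- .read_pnm_ascii(path)
  } else {
    stop("unsupported mask format: .", ext, " (use png, pgm or pbm)")
  }
  raster_mask(m, pixel_size = pixel_size, origin = origin)
}

#' Write a binary mask image
#'
#' PNG (8-bit grayscale, 0/255) or ASCII PGM (`P2`, used for plain-text
#' fixtures). A YAML sidecar `<path>.yaml` carrying `pixel_size` and `origin`
#' is written alongside unless `sidecar = FALSE`. Round trips preserve the
#' foreground set exactly.
#'
#' @param mask a `raster_mask`.
#' @param path output file; format chosen by extension (.png/.pgm).
#' @param sidecar write the metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, sidecar = TRUE) {
  stopifnot(inherits(mask, "raster_mask"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(mask$mask * 1, path)
  } else if (ext == "pgm") {
    .write_pnm_ascii(mask$mask, path)
  } else {
    stop("unsupported mask format: .", ext)
  }
  if (sidecar)
    yaml::write_yaml(list(pixel_size = mask$pixel_size,
                          origin = as.numeric(mask$origin)),
                     paste0(path, ".yaml"))
  invisible(path)
}

# minimal plain-text (ASCII) PGM/PBM reader: P1 or P2, '#' comments allowed
.read_pnm_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- unlist(strsplit(paste(txt, collapse = " "), "[[:space:]]+"))
  tok <- tok[nzchar(tok)]
  magic <- tok[1]
  if (!magic %in% c("P1", "P2")) stop("unsupported PNM magic: ", magic)
  nc <- as.integer(tok[2]); nr <- as.integer(tok[3])
  vals <- if (magic == "P2") as.integer(tok[-(1:4)]) else as.integer(tok[-(1:3)])
  if (length(vals) != nr * nc) stop("corrupt PNM: expected ", nr * nc,
                                    " values, got ", length(vals))
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE) != 0
}

.write_pnm_ascii <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "1"), con)
  apply(m * 1L, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
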