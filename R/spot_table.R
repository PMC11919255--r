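#' Spot table: one record per detected mRNA molecule
#'
#' The universal input of the pipeline: per-molecule records of gene identity
#' and 2D world coordinates in micrometres, plus a sample identifier. An
#' optional `z` column is preserved on round trip but ignored by all 2D
#' analyses (tissue sections are thin relative to lateral extent).
#'
#' @param df data.frame with columns `gene`, `x`, `y` and optionally `z`,
#'   `sample` (missing `sample` is filled with `"sample1"`).
#' @param panel a [gene_panel()] (or character vector); every gene must belong
#'   to it.
#' @return a `spot_table` (data.frame subclass with a `panel` attribute).
#' @export
spot_table <- function(df, panel) {
  panel <- .as_panel(panel)
  df <- as.data.frame(df)
  need <- c("gene", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"sample" %in% names(df)) df$sample <- "sample1"
  df$gene <- as.character(df$gene)
  df$sample <- as.character(df$sample)
  for (col in intersect(c("x", "y", "z"), names(df))) {
    if (!is.numeric(df[[col]]))
      stop("column '", col, "' must be numeric")
    if (nrow(df) && any(!is.finite(df[[col]])))
      stop("non-finite values in coordinate column '", col, "'")
  }
  bad <- setdiff(unique(df$gene), unclass(panel))
  if (length(bad))
    stop("genes outside the declared panel: ", paste(bad, collapse = ", "))
  keep <- intersect(c("gene", "x", "y", "z", "sample"), names(df))
  df <- df[, keep, drop = FALSE]
  rownames(df) <- NULL
  structure(df, panel = panel, class = c("spot_table", "data.frame"))
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("<spot_table> %d spots, %d/%d panel genes, %d sample(s)\n",
              nrow(x), length(unique(x$gene)), length(attr(x, "panel")),
              length(unique(x$sample))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Panel of a spot table
#' @param spots a `spot_table`.
#' @return the attached `gene_panel`.
#' @export
spot_panel <- function(spots) attr(spots, "panel")

#' Subset a spot table by gene
#' @param spots a `spot_table`.
#' @param genes character vector of panel genes.
#' @return a `spot_table` restricted to `genes` (panel unchanged).
#' @export
spots_for_genes <- function(spots, genes) {
  bad <- setdiff(genes, unclass(spot_panel(spots)))
  if (length(bad)) stop("not in panel: ", paste(bad, collapse = ", "))
  out <- spots[spots$gene %in% genes, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, panel = spot_panel(spots), class = class(spots))
}

#' Read a spot table from delimited text
#'
#' Expects a header naming the gene and coordinate columns; the mapping is
#' configurable via `columns`. Rows whose gene is not in the panel are dropped
#' with a message reporting the count. Coordinates are taken as micrometres
#' unless a px-to-um `scale` is supplied, in which case x/y (and z) are
#' multiplied by it.
#'
#' @param path delimited text file (TSV/CSV; separator sniffed by
#'   `data.table::fread` unless `sep` given).
#' @param panel a [gene_panel()].
#' @param columns named character vector mapping the roles `gene`, `x`, `y`
#'   (and optionally `z`, `sample`) to file column names.
#' @param scale optional multiplicative factor converting file coordinate
#'   units to um (e.g. `0.138` for pixel coordinates).
#' @param sep field separator; `"auto"` lets fread sniff it.
#' @return a `spot_table`.
#' @export
read_spot_table <- function(path, panel,
                            columns = c(gene = "gene", x = "x", y = "y",
                                        z = "z", sample = "sample"),
                            scale = NULL, sep = "auto") {
  panel <- .as_panel(panel)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  need <- c("gene", "x", "y")
  have <- columns[intersect(names(columns), names(columns))]
  missing_cols <- need[!(columns[need] %in% names(dt))]
  if (length(missing_cols))
    stop("input lacks required column(s): ",
         paste(columns[missing_cols], collapse = ", "))
  out <- data.frame(gene = as.character(dt[[columns[["gene"]]]]),
                    stringsAsFactors = FALSE)
  for (role in c("x", "y", "z")) {
    cn <- columns[role]
    if (is.na(cn) || !(cn %in% names(dt))) next
    raw <- dt[[cn]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at row %d: '%s'",
                   cn, bad[1], raw[bad[1]]))
    out[[role]] <- num
  }
  sc <- columns["sample"]
  out$sample <- if (!is.na(sc) && sc %in% names(dt))
    as.character(dt[[sc]]) else "sample1"
  off <- !(out$gene %in% unclass(panel))
  if (any(off)) {
    message("read_spot_table: dropped ", sum(off),
            " spot(s) with genes outside the panel")
    out <- out[!off, , drop = FALSE]
  }
  if (!is.null(scale)) {
    .assert_scalar_num(scale, "scale", positive = TRUE)
    for (col in intersect(c("x", "y", "z"), names(out)))
      out[[col]] <- out[[col]] * scale
  }
  spot_table(out, panel)
}

#' Write a spot table as TSV
#'
#' @param spots a `spot_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  stopifnot(inherits(spots, "spot_table"))
  df <- as.data.frame(spots)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
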