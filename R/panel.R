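#' Gene panel
#'
#' An ordered set of gene identifiers declared for a run. Every spot table is
#' validated against a panel; identifiers are compared case-sensitively (fly
#' gene symbols are case-meaningful, e.g. svp vs Svp).
#'
#' @param genes character vector of unique, non-empty identifiers.
#' @param metadata optional data.frame with one row per gene (e.g. an expected
#'   spatial pattern label for synthetic scenes); must have `nrow == length(genes)`.
#' @return a `gene_panel` object (character vector with optional metadata attr).
#' @export
gene_panel <- function(genes, metadata = NULL) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("panel must contain at least one gene")
  if (anyNA(genes) || any(!nzchar(genes)))
    stop("gene identifiers must be non-empty")
  if (anyDuplicated(genes))
    stop("gene identifiers must be unique: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != length(genes))
      stop("metadata must have one row per gene")
    rownames(metadata) <- genes
  }
  structure(genes, metadata = metadata, class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", length(x), " genes: ",
      paste(utils::head(unclass(x), 6), collapse = ", "),
      if (length(x) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

.as_panel <- function(panel) {
  if (inherits(panel, "gene_panel")) panel else gene_panel(panel)
}
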