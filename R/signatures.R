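#' Gene-set configuration for signature scoring
#'
#' Named gene sets ("categories") plus a conflict-resolution hierarchy
#' (highest priority first). Genes absent from the panel are dropped with a
#' message; a category left with no in-panel genes is a configuration error.
#' A gene may belong to several categories and then counts in each.
#'
#' @param sets named list of character vectors (category -> genes).
#' @param hierarchy character vector containing every category exactly once,
#'   highest priority first; defaults to `names(sets)` order.
#' @param z_threshold assignment threshold on z-scores (default 1).
#' @param panel optional [gene_panel()] used to validate the sets.
#' @return a `gene_set_config`.
#' @export
gene_set_config <- function(sets, hierarchy = names(sets), z_threshold = 1,
                            panel = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be named")
  if (!setequal(hierarchy, names(sets)) || anyDuplicated(hierarchy))
    stop("hierarchy must contain every category exactly once")
  sets <- lapply(sets, as.character)
  if (!is.null(panel)) {
    panel <- .as_panel(panel)
    for (nm in names(sets)) {
      off <- setdiff(sets[[nm]], unclass(panel))
      if (length(off)) {
        message("gene_set_config: dropping ", length(off),
                " off-panel gene(s) from '", nm, "': ",
                paste(off, collapse = ", "))
        sets[[nm]] <- setdiff(sets[[nm]], off)
      }
      if (length(sets[[nm]]) == 0L)
        stop("category '", nm, "' has no genes in the panel")
    }
  }
  structure(list(sets = sets, hierarchy = hierarchy,
                 z_threshold = z_threshold),
            class = "gene_set_config")
}

#' Read gene sets from YAML
#'
#' Layout: top-level `sets` (mapping category -> gene list), optional
#' `hierarchy` (list) and `z_threshold`.
#'
#' @param path YAML file.
#' @inheritParams gene_set_config
#' @return a `gene_set_config`.
#' @export
read_gene_sets <- function(path, panel = NULL) {
  y <- yaml::read_yaml(path)
  gene_set_config(y$sets, hierarchy = y$hierarchy %||% names(y$sets),
                  z_threshold = y$z_threshold %||% 1, panel = panel)
}

#' Score grid squares against gene sets
#'
#' The raw score of a square for a category is the summed expression of the
#' category's genes in that square (on whatever scale the grid carries —
#' log-normalized by convention). z-scores are computed per category across
#' all squares pooled over samples, with the population (n-denominator)
#' standard deviation. A category with zero variance across squares gets `NA`
#' z-scores and is never assigned.
#'
#' @param grid a [count_grid] (normalized recommended).
#' @param genesets a [gene_set_config()].
#' @return a `square_labels` object with `squares`, `raw` and `z` matrices
#'   (squares x categories), the grid scale used, and no labels yet (see
#'   [assign_labels()]).
#' @export
score_gene_sets <- function(grid, genesets) {
  stopifnot(inherits(grid, "count_grid"), inherits(genesets, "gene_set_config"))
  genes <- colnames(grid$counts)
  cats <- names(genesets$sets)
  ind <- matrix(0, nrow = length(genes), ncol = length(cats),
                dimnames = list(genes, cats))
  for (nm in cats) {
    gs <- intersect(genesets$sets[[nm]], genes)
    if (length(gs) == 0L)
      stop("category '", nm, "' has no genes in the grid's panel")
    ind[gs, nm] <- 1
  }
  raw <- as.matrix(grid$counts %*% ind)
  z <- raw
  for (j in seq_len(ncol(raw))) {
    s <- .sd_pop(raw[, j])
    z[, j] <- if (s > 0) (raw[, j] - mean(raw[, j])) / s else NA_real_
  }
  structure(list(squares = grid$squares, raw = raw, z = z,
                 scale = if (grid$normalized) "normalized" else "raw",
                 labels = NULL, mode = NULL,
                 z_threshold = genesets$z_threshold,
                 hierarchy = genesets$hierarchy),
            class = "square_labels")
}

#' Assign a category label to each square
#'
#' Two modes:
#' \describe{
#'   \item{`"hierarchy"` (default)}{label = highest-priority category whose
#'     z-score exceeds the threshold; `"unassigned"` when none does.}
#'   \item{`"argmax"`}{label = category with the maximal z among those above
#'     the threshold; ties broken by hierarchy order.}
#' }
#' Both modes ship because published descriptions of this procedure differ
#' between a strict hierarchy and a maximum-score rule.
#'
#' @param scores a `square_labels` from [score_gene_sets()].
#' @param mode `"hierarchy"` or `"argmax"`.
#' @param z_threshold override the configured threshold.
#' @return the `square_labels` with `labels` (character vector, one per
#'   square; `"unassigned"` allowed) and `mode` filled in.
#' @export
assign_labels <- function(scores, mode = c("hierarchy", "argmax"),
                          z_threshold = NULL) {
  stopifnot(inherits(scores, "square_labels"))
  mode <- match.arg(mode)
  thr <- z_threshold %||% scores$z_threshold
  z <- scores$z[, scores$hierarchy, drop = FALSE]  # hierarchy order
  pass <- !is.na(z) & z > thr
  labels <- rep("unassigned", nrow(z))
  any_pass <- which(rowSums(pass) > 0)
  if (length(any_pass)) {
    if (mode == "hierarchy") {
      first <- apply(pass[any_pass, , drop = FALSE], 1, which.max)
      labels[any_pass] <- colnames(z)[first]
    } else {
      zmask <- z
      zmask[!pass] <- -Inf
      # which.max returns the first (= highest-priority) maximum on ties
      best <- apply(zmask[any_pass, , drop = FALSE], 1, which.max)
      labels[any_pass] <- colnames(z)[best]
    }
  }
  scores$labels <- labels
  scores$mode <- mode
  scores
}

#' @export
print.square_labels <- function(x, ...) {
  cat(sprintf("<square_labels> %d squares x %d categories (%s scale)\n",
              nrow(x$z), ncol(x$z), x$scale))
  if (!is.null(x$labels)) {
    tab <- sort(table(x$labels), decreasing = TRUE)
    cat("  labels (", x$mode, "): ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Export square labels as TSV
#'
#' One row per square: id, sample, centroid, label and per-category z-scores.
#'
#' @param labels a labelled `square_labels`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_square_labels <- function(labels, path) {
  stopifnot(inherits(labels, "square_labels"))
  if (is.null(labels$labels)) stop("run assign_labels() first")
  df <- cbind(labels$squares[, c("square_id", "sample", "cx", "cy")],
              label = labels$labels,
              as.data.frame(labels$z))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Published body gene sets for the adult fly
#'
#' The marker-gene categories used for whole-body section annotation, with
#' the conflict hierarchy muscle > epithelia > glia > neurons > male
#' reproductive system > fat body > oenocyte > hemocyte > heart. FASN2
#' deliberately appears in both fat body and oenocyte sets.
#'
#' @param z_threshold assignment threshold (default 1).
#' @return a [gene_set_config()].
#' @export
fly_body_gene_sets <- function(z_threshold = 1) {
  sets <- list(
    muscle = c("Mhc", "sls", "CG32121"),
    epithelia = c("grh", "hth", "alphaTry", "betaTry"),
    glia = c("repo", "alrm"),
    neurons = c("elav", "Syt1", "Sh", "acj6", "ey", "VAChT", "Gad1", "VGlut",
                "nAChRalpha7"),
    `male reproductive system` = c("Awh", "eyg", "svp"),
    `fat body` = c("AkhR", "FASN2"),
    oenocyte = "FASN2",
    hemocyte = "Hml",
    heart = c("tin", "Hand"))
  gene_set_config(sets,
                  hierarchy = c("muscle", "epithelia", "glia", "neurons",
                                "male reproductive system", "fat body",
                                "oenocyte", "hemocyte", "heart"),
                  z_threshold = z_threshold)
}
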