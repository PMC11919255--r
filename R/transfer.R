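#' Cluster mean-expression profiles
#'
#' A clusters-by-genes matrix of mean expression from a single-cell
#' reference, used as the design of the nonnegative lasso.
#'
#' @param m numeric matrix (clusters x genes) with row and column names; no
#'   negative values.
#' @return a `cluster_profiles` object.
#' @export
cluster_profiles <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("profiles need cluster rownames and gene colnames")
  if (any(m < 0)) stop("profiles must be nonnegative")
  structure(m, class = c("cluster_profiles", "matrix", "array"))
}

#' Read cluster profiles from TSV (clusters x genes, first column = cluster)
#' @param path TSV file.
#' @return a `cluster_profiles`.
#' @export
read_cluster_profiles <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  cluster_profiles(m)
}

# nonnegative lasso by cyclic coordinate descent:
#   min_w >= 0   1/(2n) * ||y - X w||^2 + lambda * sum(w)
# precomputed G = X'X/n, b = X'y/n
.nnlasso_cd <- function(G, b, lambda, max_iter = 10000L, tol = 1e-8) {
  p <- length(b)
  w <- numeric(p)
  Gw <- numeric(p)
  dG <- diag(G)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (dG[j] <= 0) next
      wj <- max(0, (b[j] - Gw[j] + dG[j] * w[j] - lambda) / dG[j])
      if (wj != w[j]) {
        Gw <- Gw + G[, j] * (wj - w[j])
        delta <- max(delta, abs(wj - w[j]))
        w[j] <- wj
      }
    }
    if (delta < tol) return(list(w = w, converged = TRUE, iterations = it))
  }
  list(w = w, converged = FALSE, iterations = max_iter)
}

#' Nonnegative-lasso label transfer from cluster profiles to grid squares
#'
#' Each square's expression vector is regressed on the cluster profiles under
#' a positivity constraint with an L1 penalty (objective
#' `1/(2n) * ||y - X w||^2 + penalty * sum(w)` over `w >= 0`, the sklearn
#' Lasso scaling with `positive = TRUE`; solved per square by cyclic
#' coordinate descent). Higher weights mean higher similarity between the
#' cluster and the square. A square is assigned to the cluster with the
#' highest weight, provided that weight exceeds `weight_threshold` (strict,
#' default 0.2); otherwise it stays unassigned. Ties at the maximum are
#' broken by lexical cluster-name order (reported via `ties`). Non-converged
#' fits are flagged and left unassigned.
#'
#' @param grid a normalized [count_grid] (a warning is issued on raw counts).
#' @param profiles a [cluster_profiles()]; gene columns are matched to the
#'   grid's panel (shared genes used, >= 2 required).
#' @param penalty L1 penalty (default 1).
#' @param weight_threshold confident-match threshold (default 0.2).
#' @param max_iter,tol coordinate-descent controls.
#' @return a `transfer_result`: `weights` (squares x clusters, all >= 0),
#'   `assigned` (character, `NA` = unassigned), `converged`, `shared_genes`,
#'   `weight_threshold`.
#' @export
lasso_transfer <- function(grid, profiles, penalty = 1,
                           weight_threshold = 0.2,
                           max_iter = 10000L, tol = 1e-8) {
  stopifnot(inherits(grid, "count_grid"))
  profiles <- cluster_profiles(profiles)
  .assert_scalar_num(penalty, "penalty", positive = TRUE)
  if (!grid$normalized)
    warning("grid is not normalized; the transfer is calibrated for ",
            "log-normalized expression")
  shared <- intersect(colnames(grid$counts), colnames(profiles))
  if (length(shared) < 2L)
    stop("need at least 2 genes shared between grid and profiles (have ",
         length(shared), ")")
  X <- t(unclass(profiles)[, shared, drop = FALSE])  # genes x clusters
  Y <- as.matrix(grid$counts[, shared, drop = FALSE])
  n <- nrow(X)
  G <- crossprod(X) / n
  clusters <- colnames(X)
  nsq <- nrow(Y)
  W <- matrix(0, nsq, ncol(X), dimnames = list(rownames(Y), clusters))
  converged <- logical(nsq)
  B <- crossprod(X, t(Y)) / n  # clusters x squares of X'y/n, in one pass
  for (i in seq_len(nsq)) {
    fit <- .nnlasso_cd(G, B[, i], penalty, max_iter, tol)
    W[i, ] <- fit$w
    converged[i] <- fit$converged
  }
  ord <- order(clusters)  # lexical tie-break: scan in name order
  assigned <- rep(NA_character_, nsq)
  ties <- integer(0)
  for (i in seq_len(nsq)) {
    if (!converged[i]) next
    wi <- W[i, ord]
    mx <- max(wi)
    if (mx > weight_threshold) {
      hit <- which(wi == mx)
      if (length(hit) > 1L) ties <- c(ties, i)
      assigned[i] <- clusters[ord][hit[1L]]
    }
  }
  if (length(ties))
    message("lasso_transfer: ", length(ties),
            " square(s) had tied maximal weights (lexical tie-break)")
  structure(list(weights = W, assigned = assigned, converged = converged,
                 shared_genes = shared, weight_threshold = weight_threshold,
                 penalty = penalty),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> %d squares x %d clusters; %d assigned (threshold %g)\n",
              nrow(x$weights), ncol(x$weights), sum(!is.na(x$assigned)),
              x$weight_threshold))
  invisible(x)
}

#' Write transfer assignments as TSV (square id, assigned cluster, top weights)
#'
#' @param result a `transfer_result`.
#' @param path output file.
#' @param top number of per-square top weights to include (default 5).
#' @return `path`, invisibly.
#' @export
write_transfer_result <- function(result, path, top = 5L) {
  stopifnot(inherits(result, "transfer_result"))
  W <- result$weights
  top <- min(top, ncol(W))
  tops <- t(apply(W, 1, function(w) {
    o <- order(w, decreasing = TRUE)[seq_len(top)]
    paste0(colnames(W)[o], ":", formatC(w[o], digits = 4, format = "g"))
  }))
  df <- data.frame(square_id = rownames(W) %||% seq_len(nrow(W)),
                   assigned = ifelse(is.na(result$assigned), "unassigned",
                                     result$assigned))
  for (k in seq_len(top)) df[[paste0("weight", k)]] <- tops[, k]
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Gene-gene correlation concordance between two modalities
#'
#' Computes each modality's gene-gene Pearson correlation matrix over the
#' shared genes and returns the Pearson correlation between the strictly
#' upper-triangular entries of the two matrices — a single number summarizing
#' how well co-expression structure is preserved across modalities. Genes
#' with zero variance in either modality are excluded and counted.
#'
#' @param matrix_srt,matrix_sc observations x genes matrices (any observation
#'   counts) with gene column names; >= 3 shared genes required.
#' @return list with `r`, `n_genes`, `n_pairs`, `dropped_genes`.
#' @export
gene_correlation_concordance <- function(matrix_srt, matrix_sc) {
  m1 <- as.matrix(matrix_srt); m2 <- as.matrix(matrix_sc)
  shared <- intersect(colnames(m1), colnames(m2))
  if (length(shared) < 3L)
    stop("need at least 3 shared genes (have ", length(shared), ")")
  m1 <- m1[, shared, drop = FALSE]
  m2 <- m2[, shared, drop = FALSE]
  var1 <- matrixStats::colVars(m1)
  var2 <- matrixStats::colVars(m2)
  ok <- var1 > 0 & var2 > 0
  dropped <- shared[!ok]
  use <- shared[ok]
  if (length(use) < 3L)
    stop("fewer than 3 shared genes with nonzero variance in both modalities")
  c1 <- stats::cor(m1[, use, drop = FALSE])
  c2 <- stats::cor(m2[, use, drop = FALSE])
  ut <- upper.tri(c1)
  list(r = stats::cor(c1[ut], c2[ut]),
       n_genes = length(use), n_pairs = sum(ut),
       dropped_genes = dropped)
}
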