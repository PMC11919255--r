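`%||%` <- function(a, b) if (is.null(a)) b else a

.datatable.aware <- TRUE

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items.
#' Used to score recovered gene clusters against a ground-truth grouping
#' (1 = identical partitions up to relabelling, 0 = expected under chance).
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

# population (n-denominator) standard deviation
.sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

.assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
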