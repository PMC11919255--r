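# helper: wrap a squares x genes value matrix as a normalized count_grid
.as_grid <- function(Y) {
  genes <- colnames(Y)
  counts <- methods::as(Matrix::Matrix(Y, sparse = TRUE), "CsparseMatrix")
  rownames(counts) <- rownames(Y) %||% paste0("sq", seq_len(nrow(Y)))
  squares <- data.frame(square_id = rownames(counts), sample = "s1",
                        ix = seq_len(nrow(Y)), iy = 0L,
                        cx = 0, cy = 0, total = rowSums(Y))
  structure(list(counts = counts, squares = squares, side = 4.968,
                 normalized = TRUE, panel = gene_panel(genes)),
            class = "count_grid")
}

# distinct nonnegative profiles on a log-normalized-like scale
.make_profiles <- function(k = 8, g = 40, hi = 6, lo = 0.5) {
  m <- matrix(lo, k, g, dimnames = list(paste0("c", seq_len(k)),
                                        paste0("g", seq_len(g))))
  per <- g %/% k
  for (i in seq_len(k)) m[i, ((i - 1) * per + 1):(i * per)] <- hi
  cluster_profiles(m)
}

test_that("an orthogonal design recovers its generating cluster analytically", {
  # orthogonal profiles: soft-thresholded projection is the exact solution
  prof <- cluster_profiles(
    matrix(c(4, 0, 0, 0, 0, 0,
             0, 0, 4, 0, 0, 0,
             0, 0, 0, 0, 4, 0), 3, 6, byrow = TRUE,
           dimnames = list(c("cA", "cB", "cC"), paste0("g", 1:6))))
  Y <- matrix(0, 1, 6, dimnames = list("sq1", paste0("g", 1:6)))
  Y[1, 1] <- 12  # three times cA's profile
  penalty <- 0.1
  tr <- lasso_transfer(.as_grid(Y), prof, penalty = penalty)
  n <- 6
  G_aa <- sum(prof["cA", ]^2) / n
  b_a <- sum(prof["cA", ] * Y[1, ]) / n
  expect_equal(unname(tr$weights[1, "cA"]), max(0, (b_a - penalty) / G_aa),
               tolerance = 1e-6)
  expect_equal(unname(tr$weights[1, c("cB", "cC")]), c(0, 0))
  expect_equal(tr$assigned[1], "cA")
})

test_that("all-zero squares get zero weights and stay unassigned", {
  prof <- .make_profiles(4, 20)
  Y <- matrix(0, 2, 20, dimnames = list(NULL, colnames(prof)))
  Y[2, ] <- unclass(prof)[1, ]
  tr <- lasso_transfer(.as_grid(Y), prof)
  expect_equal(unname(tr$weights[1, ]), rep(0, 4))
  expect_true(is.na(tr$assigned[1]))
  expect_equal(tr$assigned[2], "c1")
})

test_that("the confident-match threshold is strict at 0.2", {
  # single orthogonal predictor scaled so the fitted weight is exactly c - penalty/G
  prof <- cluster_profiles(matrix(c(rep(4, 5), rep(0, 5),
                                    rep(0, 5), rep(4, 5)), 2, 10, byrow = TRUE,
                                  dimnames = list(c("a", "b"), paste0("g", 1:10))))
  G <- sum(prof["a", ]^2) / 10  # = 8
  make_y <- function(cc) {
    Y <- matrix(0, 1, 10, dimnames = list(NULL, colnames(prof)))
    Y[1, 1:5] <- 4 * cc
    Y
  }
  c_low <- 0.19 + 1 / G   # weight 0.19 < 0.2 -> unassigned
  tr <- lasso_transfer(.as_grid(make_y(c_low)), prof, penalty = 1)
  expect_equal(unname(tr$weights[1, "a"]), 0.19, tolerance = 1e-6)
  expect_true(is.na(tr$assigned[1]))
  c_hi <- 0.21 + 1 / G
  tr2 <- lasso_transfer(.as_grid(make_y(c_hi)), prof, penalty = 1)
  expect_equal(tr2$assigned[1], "a")
})

test_that("coordinate descent matches the glmnet oracle on random problems", {
  set.seed(33)
  for (rep in 1:5) {
    X <- matrix(abs(rnorm(12 * 4)), 12, 4)
    y <- abs(rnorm(12))
    lam <- runif(1, 0.05, 0.5)
    ours <- spotgrid:::.nnlasso_cd(crossprod(X) / 12, crossprod(X, y) / 12, lam)
    fit <- glmnet::glmnet(X, y, lambda = lam, lower.limits = 0,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-12)
    expect_equal(ours$w, as.numeric(fit$beta), tolerance = 1e-4)
  }
})

test_that("weights are nonnegative and shrink monotonically with the penalty", {
  set.seed(44)
  prof <- .make_profiles(6, 30)
  Y <- unclass(prof)[sample(6, 20, TRUE), ] + abs(rnorm(20 * 30, 0, 0.3))
  rownames(Y) <- NULL
  grid <- .as_grid(Y)
  sums <- vapply(c(0.1, 0.5, 1, 2, 4), function(lam) {
    tr <- lasso_transfer(grid, prof, penalty = lam)
    expect_true(all(tr$weights >= 0))
    sum(tr$weights)
  }, numeric(1))
  expect_true(all(diff(sums) <= 1e-8))
})

test_that("noisy profile copies are assigned to their generating cluster", {
  set.seed(55)
  prof <- .make_profiles(8, 40)
  truth <- rep(seq_len(8), length.out = 100)
  Y <- unclass(prof)[truth, ]
  Y <- pmax(Y + matrix(rnorm(length(Y), 0, 0.1), nrow(Y)) * Y, 0)
  rownames(Y) <- NULL
  colnames(Y) <- colnames(prof)
  tr <- lasso_transfer(.as_grid(Y), prof)
  expect_gte(mean(tr$assigned == rownames(prof)[truth], na.rm = TRUE), 0.9)
  expect_gte(mean(!is.na(tr$assigned)), 0.9)
})

test_that("transfer validates inputs and round-trips profiles via TSV", {
  prof <- .make_profiles(3, 12)
  Y <- matrix(1, 2, 3, dimnames = list(NULL, c("other1", "other2", "other3")))
  expect_error(lasso_transfer(.as_grid(Y), prof), "shared between")
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(cluster = rownames(prof), unclass(prof), check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  back <- read_cluster_profiles(path)
  expect_equal(unclass(back), unclass(prof))
  expect_error(cluster_profiles(matrix(-1, 1, 1,
                                       dimnames = list("a", "g"))),
               "nonnegative")
  out <- withr::local_tempfile(fileext = ".tsv")
  tr <- lasso_transfer(.as_grid(unclass(prof)), prof)
  write_transfer_result(tr, out)
  expect_equal(nrow(data.table::fread(out)), 3L)
})

test_that("concordance r is 1 for identical matrices and invariant to gene order", {
  set.seed(66)
  m <- matrix(rnorm(200 * 10), 200, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  expect_equal(gene_correlation_concordance(m, m)$r, 1)
  perm <- sample(10)
  r1 <- gene_correlation_concordance(m, m[, perm])$r
  expect_equal(r1, 1)  # matching is by gene name, so order cannot matter
  expect_error(gene_correlation_concordance(m[, 1:2], m[, 1:2]), "at least 3")
})

test_that("zero-variance genes are excluded and counted", {
  set.seed(8)
  m1 <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("g", 1:5)))
  m2 <- m1
  m2[, "g2"] <- 7  # constant in modality 2 only
  out <- gene_correlation_concordance(m1, m2)
  expect_equal(out$dropped_genes, "g2")
  expect_equal(out$n_genes, 4)
  expect_equal(out$n_pairs, choose(4, 2))
})

test_that("independently permuted columns destroy concordance (null band)", {
  set.seed(77)
  n <- 2000; g <- 50
  base <- matrix(rnorm(n * 3), n, 3)
  load <- matrix(rnorm(3 * g), 3, g)
  m1 <- base %*% load + matrix(rnorm(n * g), n, g)
  colnames(m1) <- paste0("g", seq_len(g))
  m2 <- apply(m1, 2, sample)
  colnames(m2) <- colnames(m1)
  expect_lt(abs(gene_correlation_concordance(m1, m2)$r), 0.1)
})

test_that("paired modalities sharing latent structure stay concordant (r > 0.6)", {
  set.seed(88)
  k <- 6; g <- 30
  prof <- matrix(abs(rnorm(k * g, 2, 1)), k, g)
  colnames(prof) <- paste0("g", seq_len(g))
  draw <- function(n, noise) {
    id <- sample(k, n, TRUE)
    prof[id, ] + matrix(rnorm(n * g, 0, noise), n, g)
  }
  m1 <- draw(500, 0.5)
  m2 <- draw(800, 0.5)
  colnames(m1) <- colnames(m2) <- colnames(prof)
  expect_gt(gene_correlation_concordance(m1, m2)$r, 0.6)
})
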