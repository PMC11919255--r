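# Independent oracles frozen against the implementation paths they check.

# circle-circle lens (intersection) area, radii r, center distance d
lens_area <- function(d, r) {
  if (d >= 2 * r) return(0)
  2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
}

# Monte-Carlo dart-throwing estimate of a disk-union area with binomial SE
mc_union_area <- function(xy, r, n_darts = 1e6) {
  lo <- apply(xy, 2, min) - r
  hi <- apply(xy, 2, max) + r
  box <- prod(hi - lo)
  px <- runif(n_darts, lo[1], hi[1])
  py <- runif(n_darts, lo[2], hi[2])
  inside <- rep(FALSE, n_darts)
  for (k in seq_len(nrow(xy)))
    inside <- inside | ((px - xy[k, 1])^2 + (py - xy[k, 2])^2 <= r^2)
  p <- mean(inside)
  list(area = p * box, se = sqrt(p * (1 - p) / n_darts) * box)
}

# brute-force per-square tally: double loop over spots
oracle_bin_counts <- function(x, y, gene, side) {
  key <- character(length(x))
  for (s in seq_along(x))
    key[s] <- paste(floor(x[s] / side), floor(y[s] / side), gene[s], sep = "|")
  table(key)
}

# independent morphology oracle built from literal window shifts
# (out[i, j] looks at m[i + dr, j + dc] over the kernel window, zero padded)
oracle_shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ri <- seq_len(nr) + dr
  ci <- seq_len(nc) + dc
  rok <- ri >= 1 & ri <= nr
  cok <- ci >= 1 & ci <= nc
  out[rok, cok] <- m[ri[rok], ci[cok]]
  out
}

oracle_window <- function(kh, kw) {
  expand.grid(dr = (-(kh %/% 2)):(kh - 1 - kh %/% 2),
              dc = (-(kw %/% 2)):(kw - 1 - kw %/% 2))
}

oracle_erode <- function(m, kh, kw) {
  w <- oracle_window(kh, kw)
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (k in seq_len(nrow(w)))
    out <- out & oracle_shift(m, w$dr[k], w$dc[k])
  out
}

oracle_dilate <- function(m, kh, kw) {
  w <- oracle_window(kh, kw)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (k in seq_len(nrow(w)))
    out <- out | oracle_shift(m, w$dr[k], w$dc[k])
  out
}

# exhaustive all-pairs nearest distance
oracle_nn <- function(sx, sy, px, py) {
  vapply(seq_along(sx), function(i)
    sqrt(min((sx[i] - px)^2 + (sy[i] - py)^2)), numeric(1))
}

# rule-table enumeration oracle for label assignment
oracle_assign <- function(z, hierarchy, thr, mode) {
  out <- character(nrow(z))
  for (i in seq_len(nrow(z))) {
    zi <- z[i, hierarchy]
    pass <- !is.na(zi) & zi > thr
    if (!any(pass)) { out[i] <- "unassigned"; next }
    out[i] <- if (mode == "hierarchy") hierarchy[which(pass)[1]]
              else hierarchy[which(pass & zi == max(zi[pass]))[1]]
  }
  out
}

make_spots <- function(gene, x, y, panel = NULL, sample = "s1") {
  panel <- panel %||% gene_panel(unique(gene))
  spot_table(data.frame(gene = gene, x = x, y = y,
                        sample = rep_len(sample, length(gene))), panel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
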