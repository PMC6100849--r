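# Independent brute-force oracles. Each is written from the bare
# definition, along a different route than the implementation it checks.

# Jaccard distance via explicit set operations
oracle_jaccard <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- which(m[i, ] == 1)
    b <- which(m[j, ] == 1)
    uni <- length(union(a, b))
    out[i, j] <- if (uni == 0) 0 else 1 - length(intersect(a, b)) / uni
  }
  out
}

# naive O(n^3) UPGMA: returns merge heights and the leaf partition trace
oracle_upgma_heights <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(D[clusters[[i]], clusters[[j]]])
      if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# Pearson chi-squared for a 2x2 table from cell-by-cell expected counts
oracle_chisq_2x2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Spearman rho: midranks then the plain Pearson product-moment formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact two-sided Mann-Whitney p by bitmask enumeration of group labels
oracle_mw_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  pool <- c(a, b)
  u_of <- function(ai, bi) {
    u <- 0
    for (x in ai) for (y in bi) u <- u + (x > y) + 0.5 * (x == y)
    min(u, na * nb - u)
  }
  obs <- u_of(a, b)
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) != na) next
    total <- total + 1L
    if (u_of(pool[sel], pool[-sel]) <= obs + 1e-9) hits <- hits + 1L
  }
  hits / total
}

# Pearson correlation from raw sums (for cophenetic-correlation checks)
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# vector-fit r2 by explicitly solving the normal equations
oracle_vectorfit_r2 <- function(coords, z) {
  X <- scale(coords, center = TRUE, scale = FALSE)
  zc <- z - mean(z)
  b <- solve(t(X) %*% X, t(X) %*% zc)
  sum((X %*% b)^2) / sum(zc^2)
}

# stress-1 objective used by the numerical-gradient NMDS oracle
oracle_stress1 <- function(delta, Xv, dims) {
  X <- matrix(Xv, ncol = dims)
  dd <- as.vector(dist(X))
  ord <- order(delta, dd)
  dhat <- numeric(length(dd))
  dhat[ord] <- isoreg(dd[ord])$yf
  sqrt(sum((dd - dhat)^2) / sum(dd^2))
}

# COSA group dispersion straight from the printed definition: ordered pairs
# (i = j included), divided by the squared group size
oracle_group_dispersion <- function(dijk, idx) {
  tot <- 0
  for (i in idx) for (j in idx) tot <- tot + dijk[i, j]
  tot / length(idx)^2
}
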