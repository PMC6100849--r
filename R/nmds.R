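# Kruskal-style nonmetric multidimensional scaling, written out in full so
# the optimizer, the tie treatment and the stress trace are under the
# package's control (and testable against independent oracles).

# disparities by pool-adjacent-violators monotone regression of the
# configuration distances on the rank order of the dissimilarities;
# primary treatment of ties: within a tie block of delta, distances are
# ordered ascending, so tied dissimilarities may receive distinct disparities
nmds_disparities <- function(delta, d) {
  ord <- order(delta, d)
  dhat <- numeric(length(d))
  dhat[ord] <- stats::isoreg(d[ord])$yf
  dhat
}

# Kruskal stress-1: sqrt(sum((d - dhat)^2) / sum(d^2))
nmds_stress <- function(delta, X) {
  d <- as.vector(stats::dist(X))
  dhat <- nmds_disparities(delta, d)
  sqrt(sum((d - dhat)^2) / sum(d^2))
}

# analytic gradient of stress-1 wrt the configuration, valid a.e.
# (the PAV fit is the projection of d onto the monotone cone, so
# dS/dd = 2 (d - dhat) by the projection theorem)
nmds_gradient <- function(delta, X) {
  n <- nrow(X)
  d <- as.vector(stats::dist(X))
  dhat <- nmds_disparities(delta, d)
  S <- sum((d - dhat)^2)
  T <- sum(d^2)
  f <- sqrt(S / T)
  if (f == 0) return(list(G = matrix(0, n, ncol(X)), stress = 0))
  # df/dd_k
  gd <- ((d - dhat) * T - S * d) / (f * T^2)
  G <- matrix(0, n, ncol(X))
  pairs <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  # dist() enumerates column-major lower triangle: same order as which() here
  i <- pairs[, 1L]; j <- pairs[, 2L]
  ok <- d > 0
  w <- ifelse(ok, gd / d, 0)
  for (m in seq_len(ncol(X))) {
    diffm <- (X[i, m] - X[j, m]) * w
    G[, m] <- as.vector(rowsum(c(diffm, -diffm), c(i, j),
                               reorder = TRUE))
  }
  list(G = G, stress = f)
}

nmds_descent <- function(delta, X0, max_iter, tol) {
  X <- X0
  f <- nmds_stress(delta, X)
  trace <- f
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gr <- nmds_gradient(delta, X)
    G <- gr$G
    g2 <- sum(G^2)
    if (g2 < 1e-30 || gr$stress < 1e-12) { converged <- TRUE; break }
    # backtracking line search; only decreases are ever accepted
    accepted <- FALSE
    s <- step
    for (bt in 1:40) {
      Xn <- X - s * G
      fn <- nmds_stress(delta, Xn)
      if (fn < f - 1e-4 * s * g2) { accepted <- TRUE; break }
      s <- s / 2
    }
    if (!accepted) { converged <- TRUE; break }
    improvement <- f - fn
    X <- Xn; f <- fn
    trace <- c(trace, f)
    step <- s * 2
    if (improvement < tol) { converged <- TRUE; break }
  }
  list(X = X, stress = f, trace = trace, converged = converged)
}

#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Finds a low-dimensional configuration whose inter-point distances are,
#' after monotone (pool-adjacent-violators) regression on the input
#' dissimilarity order, as close as possible to the regressed disparities:
#' stress-1 \eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}} is minimized by
#' steepest descent with backtracking line search, so the recorded stress
#' trace is nonincreasing. The best configuration over one metric-scaling
#' (classical MDS) start plus `restarts` random starts is returned, with
#' coordinates centered on the origin.
#'
#' @param d a `dist` of dissimilarities (n objects, n > dims).
#' @param dims target dimensionality (default 2).
#' @param restarts number of additional random starts (default 10).
#' @param seed integer seed controlling the random starts.
#' @param max_iter iteration cap per start.
#' @param tol stop when the per-iteration stress improvement falls below
#'   this value.
#' @return object of class `nmds_fit`: `points` (n x dims, centered),
#'   `stress`, `r2` (squared correlation between disparities and
#'   configuration distances), `trace` (stress values of the best run),
#'   `converged`, `n_restarts_used`, `seed`.
#' @export
nmds <- function(d, dims = 2, restarts = 10, seed = 1,
                 max_iter = 200, tol = 1e-8) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (n <= dims) stopf("nmds: need more objects (%d) than dimensions (%d)", n, dims)
  delta <- as.vector(d)
  set.seed(seed)

  starts <- list()
  cm <- suppressWarnings(stats::cmdscale(d, k = dims))
  if (ncol(cm) < dims)  # degenerate spectra: pad missing axes with zeros
    cm <- cbind(cm, matrix(0, n, dims - ncol(cm)))
  starts[[1L]] <- cm
  for (r in seq_len(restarts))
    starts[[r + 1L]] <- matrix(stats::rnorm(n * dims), n, dims)

  best <- NULL
  for (X0 in starts) {
    run <- nmds_descent(delta, X0, max_iter, tol)
    if (is.null(best) || run$stress < best$stress) best <- run
  }

  X <- scale(best$X, center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  labs <- attr(d, "Labels")
  if (!is.null(labs)) rownames(X) <- labs
  dd <- as.vector(stats::dist(X))
  dhat <- nmds_disparities(delta, dd)
  out <- list(points = X, stress = best$stress,
              r2 = stats::cor(dhat, dd)^2,
              trace = best$trace, converged = best$converged,
              n_restarts_used = restarts, seed = seed, dims = dims)
  class(out) <- "nmds_fit"
  out
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS (%d points, %d dims): stress-1 = %.4f, R^2 = %.4f%s\n",
              nrow(x$points), x$dims, x$stress, x$r2,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
plot.nmds_fit <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) "grey30" else as.integer(as.factor(groups))
  plot(x$points[, 1:2], xlab = "NMDS1", ylab = "NMDS2", pch = 16, col = col, ...)
  invisible(x)
}
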