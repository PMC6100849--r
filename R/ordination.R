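#' K-means grouping of ordination coordinates
#'
#' Thin wrapper around `stats::kmeans` (best of `n_init` starts by total
#' within-group sum of squares) with explicit seeding.
#'
#' @param coords numeric matrix (e.g. `nmds_fit$points`).
#' @param k number of groups (k <= n).
#' @param seed integer seed.
#' @param n_init number of random starts.
#' @return list: `labels` (named integer vector), `wss` (total within-group
#'   sum of squares), `centers`, and the underlying `kmeans` object.
#' @export
kmeans_groups <- function(coords, k, seed = 1, n_init = 25) {
  coords <- as.matrix(coords)
  stopifnot(is_count(k), k <= nrow(coords))
  if (k == nrow(coords)) {  # degenerate: every point its own group
    labels <- seq_len(nrow(coords))
    if (!is.null(rownames(coords))) names(labels) <- rownames(coords)
    return(list(labels = labels, wss = 0, centers = coords, kmeans = NULL))
  }
  set.seed(seed)
  km <- stats::kmeans(coords, centers = k, nstart = n_init, iter.max = 100)
  labels <- km$cluster
  if (!is.null(rownames(coords))) names(labels) <- rownames(coords)
  list(labels = labels, wss = km$tot.withinss, centers = km$centers, kmeans = km)
}

#' Choose the number of groups by mean silhouette width
#'
#' @param coords numeric matrix.
#' @param k_range candidate k values (within `[2, n - 1]`).
#' @param seed integer seed.
#' @param n_init starts per k.
#' @return list: `k` (the chosen value), `silhouette` (named vector of mean
#'   widths), `low_confidence` (`TRUE` when even the best mean silhouette is
#'   below 0.5; a lone cloud split by k-means typically scores ~0.3-0.4,
#'   whereas genuinely separated groups score well above 0.5). Under low
#'   confidence the smallest candidate k is returned, since the silhouette
#'   argmax is then noise.
#' @export
choose_k <- function(coords, k_range = 2:8, seed = 1, n_init = 25) {
  coords <- as.matrix(coords)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 2), all(k_range <= nrow(coords) - 1L))
  d <- stats::dist(coords)
  widths <- vapply(k_range, function(k) {
    cl <- kmeans_groups(coords, k, seed = sub_seed(seed, paste0("k", k)),
                        n_init = n_init)$labels
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  names(widths) <- k_range
  low_confidence <- max(widths) < 0.5
  best <- if (low_confidence) k_range[1L] else k_range[which.max(widths)]
  list(k = best, silhouette = widths, low_confidence = low_confidence)
}

#' Fit a numeric covariate onto an ordination by permutation
#'
#' Least-squares projection of the (centered) covariate onto the ordination
#' axes: the direction is the unit vector of regression coefficients and
#' `r2` the fraction of covariate variance explained by the configuration.
#' Significance comes from randomly permuting covariate values across
#' objects: `p = (1 + #{permuted r2 >= observed}) / (n_perm + 1)`.
#'
#' @param coords numeric matrix of ordination coordinates.
#' @param covariate numeric vector, one finite value per object.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param name covariate label carried into the result.
#' @return object of class `vector_fit`: `name`, `direction` (unit norm),
#'   `r2`, `p_value`, `n_perm`.
#' @export
fit_vector <- function(coords, covariate, n_perm = 999, seed = 1,
                       name = deparse(substitute(covariate))) {
  X <- as.matrix(coords)
  z <- as.numeric(covariate)
  stopifnot(length(z) == nrow(X), all(is.finite(z)))
  if (stats::sd(z) == 0) stopf("fit_vector: constant covariate, fit undefined")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  r2_of <- function(zz) {
    zz <- zz - mean(zz)
    sum(qr.fitted(qrX, zz)^2) / sum(zz^2)
  }
  r2 <- r2_of(z)
  b <- qr.coef(qrX, z - mean(z))
  b[is.na(b)] <- 0
  direction <- b / sqrt(sum(b^2))
  set.seed(seed)
  exceed <- 0L
  for (p in seq_len(n_perm))
    if (r2_of(z[sample.int(length(z))]) >= r2) exceed <- exceed + 1L
  out <- list(name = name, direction = as.vector(direction), r2 = r2,
              p_value = (1 + exceed) / (n_perm + 1), n_perm = n_perm,
              seed = seed)
  class(out) <- "vector_fit"
  out
}

#' @export
print.vector_fit <- function(x, ...) {
  cat(sprintf("vector fit '%s': r2 = %.4f, p = %.4g (%d permutations)\n",
              x$name, x$r2, x$p_value, x$n_perm))
  invisible(x)
}

#' Fit several covariates onto an ordination
#'
#' @param coords numeric matrix of ordination coordinates.
#' @param covariates data frame of numeric covariates (one row per object).
#' @param n_perm,seed as in [fit_vector()].
#' @return data frame: one row per covariate with `r2` and `p_value`, plus
#'   direction components.
#' @export
fit_vectors <- function(coords, covariates, n_perm = 999, seed = 1) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == nrow(coords))
  res <- lapply(names(covariates), function(nm)
    fit_vector(coords, covariates[[nm]], n_perm = n_perm,
               seed = sub_seed(seed, nm), name = nm))
  dirs <- t(vapply(res, `[[`, numeric(ncol(coords)), "direction"))
  colnames(dirs) <- paste0("dir", seq_len(ncol(coords)))
  data.frame(covariate = vapply(res, `[[`, character(1), "name"),
             r2 = vapply(res, `[[`, numeric(1), "r2"),
             p_value = vapply(res, `[[`, numeric(1), "p_value"),
             dirs, stringsAsFactors = FALSE)
}
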