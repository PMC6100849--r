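# Clustering objects on subsets of attributes (COSA): attribute-wise
# dissimilarities, the inverse-exponential (soft-minimum) distance, the
# iterative attribute-weighting scheme, and per-group attribute importance
# with a label-randomization null.

#' Attribute-wise dissimilarities
#'
#' For binary attributes `d_ijk = |x_ik - x_jk|` (0 or 1); for numeric
#' attributes `d_ijk = |x_ik - x_jk| / s_k` with `s_k` the mean absolute
#' deviation of attribute k (dispersion-free attributes get distance 0
#' everywhere and are flagged).
#'
#' @param matrix an `attribute_matrix` of binary incidences.
#' @param numeric optional data frame / matrix of numeric attributes over
#'   the same species (rownames must match).
#' @return object of class `cosa_diss`: 3-D array `d` (species x species x
#'   attribute), `labels`, `attributes`, `binary` flags, `zero_dispersion`
#'   flags, and (when all attributes are binary) the raw incidence matrix
#'   used by closed-form fast paths.
#' @export
attribute_dissimilarities <- function(matrix, numeric = NULL) {
  m <- as_attribute_matrix(matrix)
  n <- nrow(m)
  cols <- list()
  binary <- logical(0)
  zero_disp <- logical(0)
  vals <- list()
  for (k in seq_len(ncol(m))) {
    cols[[colnames(m)[k]]] <- abs(outer(m[, k], m[, k], "-"))
    binary <- c(binary, TRUE)
    zero_disp <- c(zero_disp, length(unique(m[, k])) == 1L)
    vals[[colnames(m)[k]]] <- m[, k]
  }
  if (!is.null(numeric)) {
    num <- as.matrix(numeric)
    if (!all(is.finite(num))) stopf("attribute_dissimilarities: non-finite numeric value")
    if (nrow(num) != n || (!is.null(rownames(num)) &&
                           !identical(rownames(num), rownames(m))))
      stopf("attribute_dissimilarities: numeric rows must match the binary matrix")
    for (k in seq_len(ncol(num))) {
      s <- mean(abs(num[, k] - mean(num[, k])))
      nm <- colnames(num)[k]
      if (is.null(nm)) nm <- paste0("num", k)
      if (s == 0) {
        cols[[nm]] <- base::matrix(0, n, n)
        zero_disp <- c(zero_disp, TRUE)
      } else {
        cols[[nm]] <- abs(outer(num[, k], num[, k], "-")) / s
        zero_disp <- c(zero_disp, FALSE)
      }
      binary <- c(binary, FALSE)
      vals[[nm]] <- num[, k]
    }
  }
  K <- length(cols)
  d <- array(unlist(cols, use.names = FALSE), dim = c(n, n, K),
             dimnames = list(rownames(m), rownames(m), names(cols)))
  out <- list(d = d, labels = rownames(m), attributes = names(cols),
              binary = stats::setNames(binary, names(cols)),
              zero_dispersion = stats::setNames(zero_disp, names(cols)),
              incidence = if (all(binary)) m else NULL)
  class(out) <- "cosa_diss"
  out
}

#' Inverse-exponential (soft-minimum) distance
#'
#' Aggregates attribute-wise dissimilarities as
#' \deqn{D = -\lambda \log \sum_k w_k e^{-d_k/\lambda},}
#' which interpolates between the minimum over attributes (as
#' \eqn{\lambda \to 0}) and the weighted mean (as \eqn{\lambda \to \infty}).
#' Computed through a log-sum-exp rearrangement, so both limits are
#' numerically stable.
#'
#' @param d numeric vector of attribute-wise dissimilarities for one object
#'   pair (or a matrix, one row per pair).
#' @param weights nonnegative weights summing to 1 (one per attribute).
#' @param lambda positive scale parameter.
#' @return the aggregated distance(s).
#' @export
inv_exp_distance <- function(d, weights, lambda) {
  if (lambda <= 0) stopf("inv_exp_distance: lambda must be > 0")
  if (is.matrix(d)) return(apply(d, 1L, inv_exp_distance, weights, lambda))
  stopifnot(length(d) == length(weights), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8)
    stopf("inv_exp_distance: weights must sum to 1")
  lw <- ifelse(weights > 0, log(weights), -Inf) - d / lambda
  m <- max(lw)
  -lambda * (m + log(sum(exp(lw - m))))
}

# inverse-exponential distances from object i to all objects, given i's
# weight vector; E is the n*n x K matrix exp(-d/lambda) in pair-major order
inv_exp_rows <- function(E, n, i, w, lambda) {
  v <- E[((i - 1L) * n + 1L):(i * n), , drop = FALSE] %*% w
  -lambda * log(pmax(as.vector(v), 1e-300))
}

#' Iterative COSA attribute weighting
#'
#' Starting from uniform attribute weights, alternates between (a)
#' computing all pairwise inverse-exponential distances under the current
#' per-object weights, (b) finding each object's `k_nn` nearest neighbours,
#' and (c) resetting object i's weight on attribute k proportional to
#' `exp(-S_ik / lambda)` where `S_ik` is the mean attribute-k dissimilarity
#' from i to its neighbours. Stops when the largest absolute weight change
#' drops below `tol` or after `max_iter` sweeps. The returned dissimilarity
#' matrix is the one computed in the last executed sweep (so with
#' `max_iter = 1` it is exactly the uniform-weight inverse-exponential
#' distance), symmetrized as `(D_ij + D_ji) / 2`.
#'
#' @param diss a `cosa_diss`.
#' @param lambda scale parameter (> 0), default 0.2.
#' @param k_nn neighbourhood size, default `ceiling(sqrt(n))`.
#' @param max_iter sweep cap.
#' @param tol convergence tolerance on weights.
#' @return object of class `cosa_fit`: `D` (symmetric dissimilarity matrix,
#'   zero diagonal), `weights` (object x attribute, rows sum to 1),
#'   `lambda`, `k_nn`, `n_iter`, `converged`.
#' @export
cosa_iterate <- function(diss, lambda = 0.2, k_nn = NULL, max_iter = 50,
                         tol = 1e-4) {
  stopifnot(inherits(diss, "cosa_diss"))
  if (lambda <= 0) stopf("cosa_iterate: lambda must be > 0")
  n <- length(diss$labels)
  K <- length(diss$attributes)
  if (is.null(k_nn)) k_nn <- ceiling(sqrt(n))
  if (k_nn >= n) stopf("cosa_iterate: k_nn must be < n")

  dm <- base::matrix(diss$d, nrow = n * n, ncol = K)  # pair-major flatten
  E <- exp(-dm / lambda)
  W <- base::matrix(1 / K, n, K, dimnames = list(diss$labels, diss$attributes))
  D <- base::matrix(0, n, n, dimnames = list(diss$labels, diss$labels))
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    for (i in seq_len(n)) D[, i] <- inv_exp_rows(E, n, i, W[i, ], lambda)
    # column i of D holds distances computed with object i's weights;
    # D_ij (i's view) lives at [j, i], so the symmetrization below averages
    # the two views of each pair
    Dsym <- (D + t(D)) / 2
    diag(Dsym) <- 0
    Wnew <- W
    for (i in seq_len(n)) {
      nb <- order(Dsym[i, -i])[seq_len(k_nn)]
      nb <- seq_len(n)[-i][nb]
      S_i <- colMeans(dm[(i - 1L) * n + nb, , drop = FALSE])
      wi <- exp(-S_i / lambda)
      Wnew[i, ] <- wi / sum(wi)
    }
    delta <- max(abs(Wnew - W))
    W <- Wnew
    if (delta < tol) { converged <- TRUE; break }
  }
  out <- list(D = Dsym, weights = W, lambda = lambda, k_nn = k_nn,
              n_iter = n_iter, converged = converged)
  class(out) <- "cosa_fit"
  out
}

#' @export
print.cosa_fit <- function(x, ...) {
  cat(sprintf("COSA fit: %d objects, %d attributes, lambda = %g, k_nn = %d\n",
              nrow(x$D), ncol(x$weights), x$lambda, x$k_nn))
  cat(sprintf("  %d sweep(s), %s\n", x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# normalize group labels into a named character vector over diss$labels
resolve_groups <- function(diss, groups) {
  g <- as.character(groups)
  if (!is.null(names(groups))) {
    missing_sp <- setdiff(diss$labels, names(groups))
    if (length(missing_sp))
      stopf("groups: no label for species: %s",
            paste(utils::head(missing_sp, 5L), collapse = ", "))
    g <- as.character(groups)[match(diss$labels, names(groups))]
  } else if (length(g) != length(diss$labels)) {
    stopf("groups must be named by species or aligned with the dissimilarities")
  }
  stats::setNames(g, diss$labels)
}

# S_kl for every attribute within one member set, per the ordered-pair
# (1/N^2, i = j included) convention; "unordered" divides the off-diagonal
# half-sum by choose(N, 2) instead
group_dispersion <- function(diss, idx, pairs = "ordered") {
  N <- length(idx)
  if (!is.null(diss$incidence)) {
    m1 <- colSums(diss$incidence[idx, , drop = FALSE])
    tot <- 2 * m1 * (N - m1)      # sum over ordered pairs of |xi - xj|
  } else {
    tot <- apply(diss$d[idx, idx, , drop = FALSE], 3L, sum)
  }
  if (pairs == "ordered") tot / N^2 else (tot / 2) / choose(N, 2)
}

#' Per-group attribute importance (inverse within-group dispersion)
#'
#' For each a-priori group l and attribute k the dispersion is
#' \deqn{S_{kl} = \frac{1}{N_l^2} \sum_{i,j \in C_l} d_{ijk}}
#' (sum over ordered member pairs, i = j included and contributing zero).
#' Importance is inversely proportional to dispersion,
#' `I_kl = 1 / (S_kl + epsilon)`, and relative importance normalizes
#' `I_kl` to sum to 1 within each group.
#'
#' @param diss a `cosa_diss`.
#' @param groups a-priori group labels, named by species or aligned with
#'   `diss$labels`. Every group must have >= 2 members.
#' @param epsilon regularizer for zero-dispersion attributes, for which
#'   Eq.-style inverse importance is otherwise infinite. The default 0.01
#'   caps their importance at 100: large enough to keep them top-ranked,
#'   small enough that one dispersion-free attribute cannot swamp the
#'   within-group normalization of every other attribute.
#' @param pairs `"ordered"` (the 1/N^2 convention, default) or
#'   `"unordered"` (mean over distinct pairs).
#' @return a `cosa_importance` data frame: `group`, `attribute`, `S`,
#'   `importance`, `rel_importance`.
#' @export
group_importance <- function(diss, groups, epsilon = 0.01,
                             pairs = c("ordered", "unordered")) {
  stopifnot(inherits(diss, "cosa_diss"))
  pairs <- match.arg(pairs)
  g <- resolve_groups(diss, groups)
  rows <- lapply(sort(unique(g)), function(lev) {
    idx <- which(g == lev)
    if (length(idx) < 2L)
      stopf("group_importance: group '%s' has fewer than 2 members", lev)
    S <- group_dispersion(diss, idx, pairs)
    I <- 1 / (S + epsilon)
    data.frame(group = lev, attribute = diss$attributes, S = unname(S),
               importance = unname(I),
               rel_importance = unname(I / sum(I)),
               n = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cosa_importance", "data.frame")
  out
}

#' Randomization null for COSA attribute importance
#'
#' Permutes the group labels across species `n_rand` times and recomputes
#' the importances, giving the reference distribution plotted as the "red
#' line": per group and attribute, the null mean and 95th percentile. The
#' comparison is made on the unnormalized importance scale `I = 1/(S +
#' epsilon)`: relative importances are a zero-sum share within each group,
#' so a single (near-)constant attribute would depress every other
#' attribute's share below its null and mask real syndrome members,
#' whereas unnormalized importances are compared attribute by attribute on
#' the same footing. `exceeds_null` flags an observed importance above the
#' null mean, `exceeds_p95` one above the null 95th percentile.
#'
#' @inheritParams group_importance
#' @param n_rand number of label permutations (default 1000).
#' @param seed integer seed.
#' @return a data frame: `group`, `attribute`, observed `importance` and
#'   `rel_importance`, `null_mean` and `null_p95` (of the unnormalized
#'   importance), `exceeds_null`, `exceeds_p95`.
#' @export
importance_null <- function(diss, groups, n_rand = 1000, seed = 1,
                            epsilon = 0.01,
                            pairs = c("ordered", "unordered")) {
  stopifnot(inherits(diss, "cosa_diss"), is_count(n_rand))
  pairs <- match.arg(pairs)
  g <- resolve_groups(diss, groups)
  obs <- group_importance(diss, g, epsilon = epsilon, pairs = pairs)
  levs <- sort(unique(g))
  K <- length(diss$attributes)
  acc <- array(NA_real_, dim = c(n_rand, K, length(levs)),
               dimnames = list(NULL, diss$attributes, levs))
  set.seed(seed)
  for (r in seq_len(n_rand)) {
    gp <- stats::setNames(sample(unname(g)), diss$labels)
    for (lev in levs) {
      idx <- which(gp == lev)
      S <- group_dispersion(diss, idx, pairs)
      acc[r, , lev] <- 1 / (S + epsilon)
    }
  }
  rows <- lapply(levs, function(lev) {
    o <- obs[obs$group == lev, ]
    slice <- base::matrix(acc[, , lev], nrow = n_rand, ncol = K)
    nm <- colMeans(slice)
    q95 <- apply(slice, 2L, stats::quantile, probs = 0.95, names = FALSE)
    data.frame(group = lev, attribute = o$attribute,
               importance = o$importance,
               rel_importance = o$rel_importance,
               null_mean = unname(nm), null_p95 = unname(q95),
               exceeds_null = o$importance > unname(nm),
               exceeds_p95 = o$importance > unname(q95),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Four-group COSA syndrome report for the kinship analysis
#'
#' Builds the a-priori groups ML/FL x with/without native congeneric
#' relatives from a spread classification, then runs [group_importance()]
#' and [importance_null()] over the attribute matrix and returns, per
#' group, attributes ranked by relative importance. Groups with fewer than
#' two members are reported as not computable.
#'
#' @param classification a `spread_classification` with `n_relatives`.
#' @param matrix an `attribute_matrix` over (at least) the classified
#'   species.
#' @param n_rand,seed,epsilon,lambda,k_nn see [importance_null()] and
#'   [cosa_iterate()]; the iterative weighting is run on the pooled
#'   classified species to produce the COSA dissimilarity matrix reported
#'   alongside the importances.
#' @param run_cosa logical; set `FALSE` to skip the iterative weighting.
#' @return list: `groups` (named label vector), `importance` (ranked
#'   importance table with null summaries), `not_computable` (character
#'   vector of skipped groups), `cosa` (a `cosa_fit` or `NULL`).
#' @export
dnh_syndrome_report <- function(classification, matrix, n_rand = 1000,
                                seed = 1, epsilon = 0.01, lambda = 0.2,
                                k_nn = NULL, run_cosa = TRUE) {
  stopifnot(inherits(classification, "spread_classification"),
            "n_relatives" %in% names(classification))
  m <- as_attribute_matrix(matrix)
  cl <- classification[classification$label %in% c("ML", "FL"), , drop = FALSE]
  cl <- cl[cl$species %in% rownames(m), , drop = FALSE]
  if (nrow(cl) == 0L) stopf("dnh_syndrome_report: no classified species in the matrix")
  grp <- paste0(cl$label, ifelse(cl$n_relatives > 0, "_with_rel", "_no_rel"))
  groups <- stats::setNames(grp, cl$species)

  sizes <- table(groups)
  usable <- names(sizes)[sizes >= 2]
  not_computable <- setdiff(names(sizes), usable)
  keep <- names(groups)[groups %in% usable]
  if (length(keep) < 2L) stopf("dnh_syndrome_report: no usable group")

  diss <- attribute_dissimilarities(m[keep, , drop = FALSE])
  imp <- importance_null(diss, groups[keep], n_rand = n_rand, seed = seed,
                         epsilon = epsilon)
  imp <- imp[order(imp$group, -imp$rel_importance), ]
  imp$rank <- stats::ave(-imp$rel_importance, imp$group, FUN = rank)
  rownames(imp) <- NULL

  fit <- if (run_cosa) cosa_iterate(diss, lambda = lambda, k_nn = k_nn) else NULL
  list(groups = groups, importance = imp, not_computable = not_computable,
       cosa = fit)
}
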