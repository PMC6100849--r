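#' Validate a binary species-by-attribute incidence matrix
#'
#' @param x matrix or data frame; entries must be 0/1, with unique row
#'   (species) and column (attribute) labels.
#' @return an integer matrix of class `attribute_matrix`.
#' @export
as_attribute_matrix <- function(x) {
  m <- as.matrix(x)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stopf("attribute matrix: unique species row names required")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stopf("attribute matrix: unique attribute column names required")
  storage.mode(m) <- "numeric"
  if (any(!is.finite(m)) || any(!m %in% c(0, 1)))
    stopf("attribute matrix: entries must be 0 or 1")
  storage.mode(m) <- "integer"
  class(m) <- c("attribute_matrix", class(matrix()))
  m
}

#' Read an attribute matrix from CSV/TSV
#'
#' First column = species labels, remaining columns = binary attributes.
#' @param path file path.
#' @return an `attribute_matrix`.
#' @export
read_attribute_matrix <- function(path) {
  if (!file.exists(path)) stopf("read_attribute_matrix: no such file: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          row.names = 1L, check.names = FALSE,
                          fileEncoding = "UTF-8")
  as_attribute_matrix(df)
}

#' Jaccard distances between species or between attributes
#'
#' `d(u, v) = 1 - |u & v| / |u | v|` over binary vectors, computed with
#' `stats::dist(method = "binary")`. Two all-zero vectors, for which the
#' ratio is 0/0, are assigned distance 0 (keeps such rows in the analysis
#' instead of propagating NaN); the number of affected pairs is recorded in
#' the `n_double_zero_pairs` attribute.
#'
#' @param matrix an `attribute_matrix` (or binary matrix with dimnames).
#' @param axis `"species"` (rows, the default) or `"attributes"` (columns,
#'   i.e. attribute incidence profiles across species).
#' @return a `dist` object.
#' @export
jaccard_dist <- function(matrix, axis = c("species", "attributes")) {
  axis <- match.arg(axis)
  m <- as_attribute_matrix(matrix)
  if (axis == "attributes") m <- t(m)
  d <- stats::dist(m, method = "binary")
  d[is.na(d)] <- 0  # defensive; base dist already treats 0/0 pairs as 0
  n_zero_rows <- sum(rowSums(m) == 0)
  attr(d, "n_double_zero_pairs") <- choose(n_zero_rows, 2)
  d
}

#' UPGMA clustering
#'
#' Average-linkage agglomerative clustering via `stats::hclust`. Labels are
#' sorted lexicographically before clustering so that distance ties are
#' broken by label order and runs are reproducible regardless of input
#' ordering.
#'
#' @param d a `dist` object with labels.
#' @return an `hclust` object (method `"average"`).
#' @export
upgma <- function(d) {
  stopifnot(inherits(d, "dist"))
  labs <- attr(d, "Labels")
  if (is.null(labs)) labs <- as.character(seq_len(attr(d, "Size")))
  if (attr(d, "Size") < 2L) stopf("upgma: need >= 2 objects")
  m <- as.matrix(d)
  dimnames(m) <- list(labs, labs)
  ord <- order(labs)
  stats::hclust(stats::as.dist(m[ord, ord]), method = "average")
}

#' Cophenetic distances and cophenetic correlation
#'
#' @param d the original `dist` the dendrogram was built from.
#' @param dend an `hclust` tree over the same labels.
#' @return list with `cophenetic` (a `dist`) and `correlation` (Pearson r
#'   between original and cophenetic off-diagonal entries).
#' @export
cophenetic_cor <- function(d, dend) {
  stopifnot(inherits(d, "dist"), inherits(dend, "hclust"))
  cp <- stats::cophenetic(dend)
  labs <- attr(cp, "Labels")
  m <- as.matrix(d)[labs, labs]
  r <- stats::cor(as.vector(stats::as.dist(m)), as.vector(cp))
  list(cophenetic = cp, correlation = r)
}

#' Cut a dendrogram at a height
#'
#' @param dend an `hclust` tree.
#' @param height cut height (>= 0); leaves joined strictly below it share a
#'   group.
#' @return named integer vector of group memberships.
#' @export
cut_dendrogram <- function(dend, height) {
  stopifnot(inherits(dend, "hclust"), height >= 0)
  stats::cutree(dend, h = height)
}

#' Prune attributes that do not contribute to the species classification
#'
#' Greedy leave-one-out screen: constant (all-zero or all-one) attributes
#' are dropped first; then, repeatedly, the attribute whose removal most
#' increases (or least decreases) the cophenetic correlation of the species
#' UPGMA dendrogram is dropped, as long as the correlation stays within
#' `epsilon` of the running maximum. With `epsilon = Inf` this degenerates
#' to keeping a single attribute.
#'
#' Because leave-one-out contributions cannot see redundancy (any one of a
#' set of mutually redundant structural attributes can be removed without
#' hurting the correlation), unconstrained greedy pruning can run far
#' deeper than intended; `min_retain` bounds how small the retained set may
#' become.
#'
#' @param matrix an `attribute_matrix`.
#' @param epsilon tolerated drop in cophenetic correlation (default 0.005).
#' @param min_retain stop once this many attributes remain (default 1).
#' @return list with `retained`, `dropped`, and a `report` data frame
#'   (step, attribute, cophenetic correlation after dropping).
#' @export
prune_attributes <- function(matrix, epsilon = 0.005, min_retain = 1) {
  m <- as_attribute_matrix(matrix)
  if (ncol(m) < 2L) stopf("prune_attributes: need >= 2 attributes")
  steps <- list()
  log_step <- function(attr_name, corr, why) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = length(steps) + 1L, attribute = attr_name,
      cophenetic_correlation = corr, reason = why, stringsAsFactors = FALSE)
  }
  coph <- function(cols) {
    d <- jaccard_dist(m[, cols, drop = FALSE])
    cophenetic_cor(d, upgma(d))$correlation
  }

  cols <- colnames(m)
  const <- cols[apply(m, 2L, function(v) length(unique(v)) == 1L)]
  for (a in const) {
    cols <- setdiff(cols, a)
    if (length(cols) == 0L) stopf("prune_attributes: all attributes constant")
    log_step(a, NA_real_, "constant")
  }

  current <- coph(cols)
  best_seen <- current
  while (length(cols) > max(1L, min_retain)) {
    cand <- vapply(cols, function(a) coph(setdiff(cols, a)), numeric(1))
    a_best <- names(cand)[which.max(cand)]
    if (cand[a_best] < best_seen - epsilon) break
    cols <- setdiff(cols, a_best)
    current <- cand[[a_best]]
    best_seen <- max(best_seen, current)
    log_step(a_best, current, "leave-one-out")
    if (is.na(current)) break
  }

  report <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(), attribute = character(),
               cophenetic_correlation = numeric(), reason = character())
  list(retained = cols, dropped = setdiff(colnames(m), cols), report = report,
       final_correlation = current)
}

#' Export a dendrogram as Newick
#'
#' @param dend an `hclust` tree.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  stopifnot(inherits(dend, "hclust"))
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}

#' Doubly ordered incidence matrix for heat-map rendering
#'
#' Reorders species rows and attribute columns by their respective UPGMA
#' dendrogram leaf orders.
#'
#' @param matrix an `attribute_matrix`.
#' @return list: the reordered `matrix` and the two `hclust` trees.
#' @export
heatmap_order <- function(matrix) {
  m <- as_attribute_matrix(matrix)
  hs <- upgma(jaccard_dist(m, "species"))
  ha <- upgma(jaccard_dist(m, "attributes"))
  list(matrix = m[hs$labels[hs$order], ha$labels[ha$order], drop = FALSE],
       species_tree = hs, attribute_tree = ha)
}
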