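test_that("Jaccard distances match the set-based oracle and handle double zeros", {
  m <- rbind(u = c(1, 1, 0), v = c(1, 0, 1), w = c(1, 1, 0))
  colnames(m) <- c("a", "b", "c")
  d <- as.matrix(jaccard_dist(m))
  expect_equal(d["u", "v"], 1 - 1 / 3, tolerance = 1e-12)
  expect_equal(d["u", "w"], 0)

  rm20 <- random_binary_matrix(20, 10, seed = 4)
  expect_equal(as.matrix(jaccard_dist(rm20)), oracle_jaccard(rm20),
               tolerance = 1e-12)

  # two all-zero species: 0/0 pair assigned distance zero and counted
  z <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0))
  colnames(z) <- c("x", "y")
  dz <- jaccard_dist(z)
  expect_equal(as.matrix(dz)["a", "b"], 0)
  expect_equal(attr(dz, "n_double_zero_pairs"), 1L)

  nb <- rbind(a = c(0, 2), b = c(1, 0))
  colnames(nb) <- c("x", "y")
  expect_error(jaccard_dist(nb), "0 or 1")
})

test_that("Jaccard on binary data satisfies the triangle inequality", {
  m <- random_binary_matrix(12, 6, p = 0.5, seed = 9)
  d <- as.matrix(jaccard_dist(m))
  for (i in 1:12) for (j in 1:12) for (k in 1:12)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("UPGMA reproduces forced topologies and the naive oracle", {
  d3 <- as.dist(matrix(c(0, 0.1, 0.5, 0.1, 0, 0.5, 0.5, 0.5, 0), 3, 3,
                       dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  h3 <- upgma(d3)
  expect_equal(h3$height, c(0.1, 0.5))

  set.seed(14)
  d8 <- as.dist(matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8])))
  d8[] <- runif(28, 0.1, 1)
  h8 <- upgma(d8)
  expect_equal(h8$height, oracle_upgma_heights(d8), tolerance = 1e-12)

  # invariance under label permutation of the input
  perm <- sample(8)
  dmat <- as.matrix(d8)[perm, perm]
  h8p <- upgma(as.dist(dmat))
  expect_equal(h8p$height, h8$height, tolerance = 1e-12)
})

test_that("cophenetic distances and correlation behave on ultrametric trees", {
  d3 <- as.dist(matrix(c(0, 0.1, 0.5, 0.1, 0, 0.5, 0.5, 0.5, 0), 3, 3,
                       dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  cc <- cophenetic_cor(d3, upgma(d3))
  expect_equal(as.vector(cc$cophenetic), as.vector(d3))  # UPGMA fixed point
  expect_equal(cc$correlation, 1)

  d2 <- as.dist(matrix(c(0, 0.3, 0.3, 0), 2, 2,
                       dimnames = list(c("A", "B"), c("A", "B"))))
  cc2 <- cophenetic_cor(d2, upgma(d2))
  expect_equal(as.vector(cc2$cophenetic), 0.3)

  set.seed(3)
  d8 <- as.dist(matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8])))
  d8[] <- runif(28, 0.1, 1)
  hc <- upgma(d8)
  cc8 <- cophenetic_cor(d8, hc)
  labs <- hc$labels
  orig <- as.vector(as.dist(as.matrix(d8)[labs, labs]))
  expect_equal(cc8$correlation,
               oracle_pearson(orig, as.vector(cc8$cophenetic)),
               tolerance = 1e-12)
})

test_that("dendrogram cuts return connected components below the height", {
  set.seed(6)
  d8 <- as.dist(matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8])))
  d8[] <- runif(28, 0.1, 1)
  hc <- upgma(d8)
  expect_equal(length(unique(cut_dendrogram(hc, max(hc$height) + 1))), 1L)
  expect_equal(length(unique(cut_dendrogram(hc, 0))), 8L)
  # cutting between the 3rd and 4th merge leaves 8 - 3 groups
  h <- mean(hc$height[3:4])
  expect_equal(length(unique(cut_dendrogram(hc, h))), 5L)
})

test_that("pruning drops constants first and respects the tolerance invariant", {
  m <- random_binary_matrix(15, 5, seed = 2)
  m <- cbind(m, konst = 1L)
  pr <- prune_attributes(m, epsilon = 0.005)
  expect_equal(pr$report$attribute[1], "konst")
  expect_equal(pr$report$reason[1], "constant")

  # invariant: no logged step sits more than epsilon below the running max
  steps <- pr$report[pr$report$reason == "leave-one-out", ]
  if (nrow(steps) > 1) {
    run_max <- cummax(steps$cophenetic_correlation)
    expect_true(all(steps$cophenetic_correlation >=
                      c(steps$cophenetic_correlation[1], head(run_max, -1)) -
                      0.005 - 1e-12))
  }

  # degenerate limit: epsilon = Inf prunes to a single attribute
  expect_length(prune_attributes(m, epsilon = Inf)$retained, 1L)
  # min_retain bounds the greedy depth
  expect_gte(length(prune_attributes(m, epsilon = Inf, min_retain = 3)$retained), 3L)
})

test_that("coin-flip attributes rank as the lowest contributors", {
  ok <- vapply(1:60, function(s) {
    set.seed(s)
    n <- 24
    grp <- rep(c(0L, 1L), each = n / 2)
    m <- cbind(matrix(rep(grp, 5), n, 5),
               matrix(rbinom(n * 3, 1, 0.5), n, 3))
    dimnames(m) <- list(sprintf("s%02d", 1:n),
                        c(paste0("block", 1:5), paste0("coin", 1:3)))
    pr <- prune_attributes(m, epsilon = 0.01)
    dropped <- pr$report$attribute
    first3 <- head(dropped[pr$report$reason == "leave-one-out"], 3)
    all(grepl("^coin", first3))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("dendrograms export to Newick and the heat-map ordering is consistent", {
  m <- random_binary_matrix(10, 6, seed = 12)
  hm <- heatmap_order(m)
  expect_setequal(rownames(hm$matrix), rownames(m))
  expect_setequal(colnames(hm$matrix), colnames(m))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hm$species_tree, path)
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, rownames(m))
})
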