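test_that("attribute-wise dissimilarities follow the elementwise definition", {
  m <- random_binary_matrix(6, 3, seed = 1)
  num <- cbind(size = c(1, 4, 2, 8, 3, 5))
  rownames(num) <- rownames(m)
  diss <- attribute_dissimilarities(m, numeric = num)
  expect_equal(dim(diss$d), c(6, 6, 4))

  # hand oracle: binary |xi - xj|; numeric |xi - xj| / mean abs deviation
  s_k <- mean(abs(num[, 1] - mean(num[, 1])))
  for (i in 1:6) for (j in 1:6) {
    for (k in 1:3) expect_equal(diss$d[i, j, k], abs(m[i, k] - m[j, k]))
    expect_equal(diss$d[i, j, 4], abs(num[i, 1] - num[j, 1]) / s_k)
  }
  expect_true(all(diss$d[cbind(1:6, 1:6, 1)] == 0))

  bad <- num; bad[2] <- NA
  expect_error(attribute_dissimilarities(m, numeric = bad), "finite")
})

test_that("the inverse-exponential distance interpolates min and weighted mean", {
  w <- c(0.2, 0.3, 0.5)
  d <- c(0.1, 0.7, 0.4)
  expect_equal(inv_exp_distance(rep(0.3, 3), w, 1), 0.3, tolerance = 1e-12)
  expect_equal(inv_exp_distance(d, w, 1e-6), min(d), tolerance = 1e-4)
  expect_equal(inv_exp_distance(d, w, 1e6), sum(w * d), tolerance = 1e-4)
  expect_error(inv_exp_distance(d, w, 0), "lambda")
  expect_error(inv_exp_distance(d, c(1, 1, 1), 1), "sum to 1")

  # log-sum-exp bounds: soft minimum between min and weighted mean
  set.seed(8)
  for (i in 1:25) {
    dd <- runif(4, 0, 3)
    ww <- runif(4); ww <- ww / sum(ww)
    lam <- 10^runif(1, -2, 2)
    v <- inv_exp_distance(dd, ww, lam)
    expect_gte(v, min(dd) - 1e-10)
    expect_lte(v, sum(ww * dd) + 1e-10)
  }
})

test_that("a single COSA sweep returns the uniform-weight distance", {
  m <- random_binary_matrix(8, 4, seed = 3)
  diss <- attribute_dissimilarities(m)
  fit <- cosa_iterate(diss, lambda = 0.5, k_nn = 3, max_iter = 1)
  w <- rep(0.25, 4)
  for (i in 1:8) for (j in 1:8)
    expect_equal(fit$D[i, j], inv_exp_distance(diss$d[i, j, ], w, 0.5),
                 tolerance = 1e-12)
  expect_equal(unname(rowSums(fit$weights)), rep(1, 8), tolerance = 1e-12)
  expect_equal(fit$D, t(fit$D))
  expect_true(all(diag(fit$D) == 0))
})

test_that("iterative weighting upweights a discriminating attribute block", {
  # a planted syndrome: four correlated attributes separating two groups,
  # the rest independent coin flips (the subset structure COSA targets)
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    n <- 40
    grp <- rep(0:1, each = n / 2)
    m <- cbind(matrix(rep(grp, 4), n, 4), matrix(rbinom(n * 8, 1, 0.5), n, 8))
    dimnames(m) <- list(sprintf("s%02d", 1:n),
                        c(paste0("block", 1:4), paste0("noise", 1:8)))
    fit <- cosa_iterate(attribute_dissimilarities(m), lambda = 0.2)
    wbar <- colMeans(fit$weights)
    min(wbar[1:4]) > max(wbar[-(1:4)])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pure-noise attributes keep near-uniform weights", {
  devs <- vapply(1:20, function(s) {
    m <- random_binary_matrix(30, 6, p = 0.5, seed = 100 + s)
    fit <- cosa_iterate(attribute_dissimilarities(m), lambda = 0.2)
    mean(abs(fit$weights - 1 / 6))
  }, numeric(1))
  expect_lt(mean(devs), 2 / 6)
})

test_that("group dispersion and importance follow the ordered-pair formula", {
  m <- matrix(c(0L, 1L), 2, 1, dimnames = list(c("x", "y"), "a"))
  diss <- attribute_dissimilarities(m)
  gi <- group_importance(diss, c(x = "g", y = "g"))
  expect_equal(gi$S, 0.5)  # (0 + 1 + 1 + 0) / 4

  # constant attribute inside the group: dispersion 0, importance 1/epsilon
  m2 <- cbind(a = c(0L, 1L, 0L, 1L), b = c(1L, 1L, 1L, 1L))
  rownames(m2) <- letters[1:4]
  gi2 <- group_importance(attribute_dissimilarities(m2),
                          setNames(rep("g", 4), letters[1:4]), epsilon = 1e-9)
  expect_equal(gi2$S[gi2$attribute == "b"], 0)
  expect_equal(gi2$importance[gi2$attribute == "b"], 1e9)

  # two attributes with equal dispersion share relative importance equally
  m3 <- cbind(a = c(0L, 1L, 0L, 1L), b = c(1L, 0L, 1L, 0L))
  rownames(m3) <- letters[1:4]
  gi3 <- group_importance(attribute_dissimilarities(m3),
                          setNames(rep("g", 4), letters[1:4]))
  expect_equal(gi3$rel_importance, c(0.5, 0.5))

  expect_error(group_importance(diss, c(x = "g1", y = "g2")), "fewer than 2")
})

test_that("dispersion matches the brute-force oracle on both code paths", {
  m <- random_binary_matrix(10, 4, seed = 6)
  diss <- attribute_dissimilarities(m)
  g <- setNames(rep(c("p", "q"), each = 5), rownames(m))
  gi <- group_importance(diss, g)
  # general path: drop the incidence shortcut and recompute
  diss_slow <- diss; diss_slow$incidence <- NULL
  gi_slow <- group_importance(diss_slow, g)
  expect_equal(gi, gi_slow, tolerance = 1e-12)
  for (lev in c("p", "q")) for (k in 1:4) {
    o <- oracle_group_dispersion(diss$d[, , k], which(g == lev))
    expect_equal(gi$S[gi$group == lev][k], o, tolerance = 1e-12)
  }
  # unordered-pair option: mean over distinct pairs
  gi_u <- group_importance(diss, g, pairs = "unordered")
  idx <- which(g == "p")
  pairsum <- 0
  for (a in idx) for (b in idx) if (a < b) pairsum <- pairsum + diss$d[a, b, 2]
  expect_equal(gi_u$S[gi_u$group == "p"][2], pairsum / choose(5, 2),
               tolerance = 1e-12)
})

test_that("importance scales inversely with attribute dissimilarity magnitude", {
  m <- random_binary_matrix(8, 3, seed = 11)
  diss <- attribute_dissimilarities(m)
  g <- setNames(rep("g", 8), rownames(m))
  base <- group_importance(diss, g, epsilon = 0)
  doubled <- diss
  doubled$incidence <- NULL
  doubled$d[, , 2] <- 2 * doubled$d[, , 2]
  gi2 <- group_importance(doubled, g, epsilon = 0)
  expect_equal(gi2$importance[2], base$importance[2] / 2, tolerance = 1e-12)
  expect_equal(gi2$importance[1], base$importance[1], tolerance = 1e-12)
})

test_that("the randomization null is reproducible and defined for n_rand = 1", {
  m <- random_binary_matrix(12, 4, seed = 2)
  diss <- attribute_dissimilarities(m)
  g <- setNames(rep(c("p", "q"), each = 6), rownames(m))
  n1 <- importance_null(diss, g, n_rand = 50, seed = 9)
  n2 <- importance_null(diss, g, n_rand = 50, seed = 9)
  expect_identical(n1, n2)
  n3 <- importance_null(diss, g, n_rand = 1, seed = 9)
  expect_true(all(is.finite(n3$null_mean)))
  expect_true(all(is.finite(n3$null_p95)))
})

test_that("randomly assigned groups are calibrated against their own null", {
  res <- vapply(1:30, function(s) {
    m <- random_binary_matrix(24, 6, p = 0.4, seed = 200 + s)
    diss <- attribute_dissimilarities(m)
    set.seed(s)
    g <- setNames(sample(rep(c("p", "q"), each = 12)), rownames(m))
    nn <- importance_null(diss, g, n_rand = 100, seed = s)
    c(mean(nn$exceeds_null), mean(nn$exceeds_p95))
  }, numeric(2))
  # observed importance is one draw from the (right-skewed) null, so it
  # beats the null mean somewhat less than half the time ...
  expect_gt(mean(res[1, ]), 0.1)
  expect_lt(mean(res[1, ]), 0.6)
  # ... and the 95th percentile about 5% of the time
  expect_lt(mean(res[2, ]), 0.15)
})

test_that("the four-group syndrome report flags planted syndromes and tiny groups", {
  set.seed(33)
  n <- 100
  lab <- rep(c("ML", "FL"), each = n / 2)
  rel <- rep(c(1L, 0L, 1L, 0L), each = n / 4)
  grp <- paste0(lab, ifelse(rel > 0, "_with_rel", "_no_rel"))
  spec <- list(ML_with_rel = list(attributes = 1:4, prob = 0.98),
               FL_with_rel = list(attributes = 5:8, prob = 0.98))
  m <- plant_attributes(setNames(grp, sprintf("sp%03d", 1:n)), 12, spec,
                        base_prob = 0.3, seed = 44)
  cls <- make_classification(lab, rel, rnorm(n), rpois(n, 10) + 1)
  rep1 <- dnh_syndrome_report(cls, m, n_rand = 200, seed = 5)
  imp <- rep1$importance
  top <- imp[imp$group == "ML_with_rel" & imp$rank <= 4, "attribute"]
  expect_setequal(top, paste0("attr", sprintf("%02d", 1:4)))
  expect_true(all(imp[imp$group == "ML_with_rel" &
                        imp$attribute %in% top, "exceeds_null"]))

  # a one-member group is reported as not computable
  lab2 <- c(rep("ML", 5), rep("FL", 5))
  rel2 <- c(1L, rep(0L, 4), rep(1L, 5))
  cls2 <- make_classification(lab2, rel2, rnorm(10), rpois(10, 10) + 1)
  m2 <- random_binary_matrix(10, 6, seed = 3)
  rownames(m2) <- cls2$species
  rep2 <- dnh_syndrome_report(cls2, m2, n_rand = 50, seed = 2, run_cosa = FALSE)
  expect_true("ML_with_rel" %in% rep2$not_computable)
})
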