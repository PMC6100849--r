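make_nonmetric_dist <- function(n, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * 2), n, 2)
  d <- dist(X)
  d[] <- d[] * exp(rnorm(length(d), 0, 0.3))
  d
}

test_that("perfectly embeddable configurations reach near-zero stress", {
  d <- dist(cbind(seq(0, 1, length.out = 12), 0))
  fit <- nmds(d, dims = 2, restarts = 2, seed = 3)
  expect_lt(fit$stress, 1e-3)
  expect_true(all(abs(colMeans(fit$points)) < 1e-8))  # centered
})

test_that("the stress trace is nonincreasing and runs are seed-reproducible", {
  d <- make_nonmetric_dist(15, 5)
  fit <- nmds(d, dims = 2, restarts = 3, seed = 11)
  expect_true(all(diff(fit$trace) <= 0))
  fit2 <- nmds(d, dims = 2, restarts = 3, seed = 11)
  expect_identical(fit$points, fit2$points)
  expect_identical(fit$stress, fit2$stress)
})

test_that("final stress matches an independent numerical-gradient oracle", {
  d <- make_nonmetric_dist(15, 5)
  fit <- nmds(d, dims = 2, restarts = 0, seed = 1, max_iter = 2000,
              tol = 1e-12)
  delta <- as.vector(d)
  X0 <- cmdscale(d, k = 2)  # same deterministic start as the implementation
  o <- optim(as.vector(X0), function(v) oracle_stress1(delta, v, 2),
             method = "BFGS", control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(fit$stress, o$value, tolerance = 1e-6)
})

test_that("stress is invariant under rotation/reflection of the start", {
  d <- make_nonmetric_dist(12, 8)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  X0 <- cmdscale(d, k = 2)
  s1 <- weedspread:::nmds_descent(as.vector(d), X0, 2000, 1e-12)$stress
  s2 <- weedspread:::nmds_descent(as.vector(d), X0 %*% R, 2000, 1e-12)$stress
  expect_lt(abs(s1 - s2), 1e-9)
})

test_that("stress agrees with an established NMDS implementation", {
  skip_if_not_installed("vegan")
  d <- make_nonmetric_dist(15, 5)
  fit <- nmds(d, dims = 2, restarts = 10, seed = 2)
  mm <- vegan::monoMDS(d, k = 2, model = "global")
  # same objective, more restarts here: never worse, and in the same basin
  expect_lte(fit$stress, mm$stress + 1e-6)
  expect_lt(abs(fit$stress - mm$stress), 0.05)
})

test_that("k-means grouping recovers separated clouds and degenerate cases", {
  set.seed(20)
  pts <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
               matrix(rnorm(40, 5, 0.2), ncol = 2))
  rownames(pts) <- sprintf("p%02d", 1:40)
  truth <- rep(1:2, each = 20)
  km <- kmeans_groups(pts, 2, seed = 1)
  expect_equal(length(unique(paste(km$labels, truth))), 2L)  # exact match up to relabeling

  expect_equal(kmeans_groups(pts, nrow(pts), seed = 1, n_init = 1)$wss, 0,
               tolerance = 1e-12)

  # objective never beaten by random partitions
  set.seed(2)
  pts30 <- matrix(rnorm(60), 30, 2)
  km3 <- kmeans_groups(pts30, 3, seed = 4)
  wss_of <- function(lbl) sum(vapply(unique(lbl), function(g) {
    sub <- pts30[lbl == g, , drop = FALSE]
    sum(scale(sub, scale = FALSE)^2)
  }, numeric(1)))
  rand <- replicate(1000, wss_of(sample(1:3, 30, replace = TRUE)))
  expect_lte(km3$wss, min(rand) + 1e-9)
})

test_that("silhouette-based k selection finds planted clouds", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    pts <- rbind(cbind(rnorm(15, 0, 0.3), rnorm(15, 0, 0.3)),
                 cbind(rnorm(15, 6, 0.3), rnorm(15, 0, 0.3)),
                 cbind(rnorm(15, 3, 0.3), rnorm(15, 5, 0.3)))
    choose_k(pts, 2:6, seed = s)$k == 3
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # single cloud: minimal k, flagged low-confidence
  set.seed(4)
  cloud <- matrix(rnorm(80), 40, 2)
  ck <- choose_k(cloud, 2:5, seed = 1)
  expect_equal(ck$k, 2L)
  expect_true(ck$low_confidence)
  expect_equal(choose_k(cloud, 4, seed = 1)$k, 4L)  # width-1 range
})

test_that("vector fitting reproduces its r2 oracle and permutation floor", {
  set.seed(31)
  coords <- matrix(rnorm(24), 12, 2)
  z <- coords[, 1]
  vf <- fit_vector(coords, z, n_perm = 199, seed = 1)
  expect_equal(vf$r2, 1, tolerance = 1e-10)
  expect_equal(vf$p_value, 1 / 200)
  expect_equal(sqrt(sum(vf$direction^2)), 1, tolerance = 1e-12)

  z2 <- rnorm(12)
  vf2 <- fit_vector(coords, z2, n_perm = 99, seed = 2)
  expect_equal(vf2$r2, oracle_vectorfit_r2(coords, z2), tolerance = 1e-10)
  expect_gte(vf2$p_value, 1 / 100)
  expect_error(fit_vector(coords, rep(1, 12), n_perm = 9), "constant")
})

test_that("vector-fit r2 agrees with the established envfit implementation", {
  skip_if_not_installed("vegan")
  set.seed(77)
  coords <- matrix(rnorm(40), 20, 2)
  z <- coords %*% c(1, 0.5) + rnorm(20, 0, 0.5)
  vf <- fit_vector(coords, as.vector(z), n_perm = 99, seed = 1)
  ev <- vegan::envfit(coords, data.frame(z = as.vector(z)), permutations = 0)
  expect_equal(vf$r2, unname(ev$vectors$r), tolerance = 1e-10)
})

test_that("null covariates give approximately uniform permutation p-values", {
  set.seed(123)
  coords <- matrix(rnorm(40), 20, 2)
  ps <- vapply(1:200, function(i)
    fit_vector(coords, rnorm(20), n_perm = 99, seed = i)$p_value, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
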