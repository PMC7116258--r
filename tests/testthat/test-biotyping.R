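test_that("pca_reduce retains the smallest component set reaching the target", {
  # two orthogonal directions carrying 80% / 20% of the variance
  set.seed(1)
  n <- 4000
  X <- cbind(2 * rnorm(n), 1 * rnorm(n)) %*% matrix(c(1, 0, 0, 1), 2)
  X <- cbind(X, 0 * rnorm(n))  # a null third column
  ratios <- prcomp(X)$sdev^2
  pc <- pca_reduce(X, var_target = 0.90)
  expect_identical(pc$n_components, 2L)
  expect_true(sum(pc$explained_ratio[1:2]) >= 0.9)
  expect_true(pc$explained_ratio[1] < 0.9)
})

test_that("isotropic gaussian data needs ~target fraction of components", {
  ncomp <- vapply(1:5, function(s) {
    set.seed(100 + s)
    pca_reduce(matrix(rnorm(3000 * 10), 3000), var_target = 0.9)$n_components
  }, integer(1))
  expect_true(all(ncomp == 9L))
})

test_that("full-rank reconstruction recovers the centred data", {
  set.seed(2)
  X <- matrix(rnorm(20 * 6), 20)
  pc <- pca_reduce(X, var_target = 1)
  recon <- pc$scores %*% t(pc$rotation)
  expect_lt(max(abs(recon - scale(X, scale = FALSE))), 1e-8)
})

test_that("variance targets outside (0, 1] are rejected", {
  X <- matrix(rnorm(40), 10)
  expect_error(pca_reduce(X, var_target = 0), "0, 1")
  expect_error(pca_reduce(X, var_target = 1.2), "0, 1")
})

test_that("correlation distance matches the elementwise formula", {
  expect_equal(correlation_distance(rbind(1:8, 1:8))[1, 2], 0)
  expect_equal(correlation_distance(rbind(1:8, -(1:8)))[1, 2], 2)
  set.seed(3)
  S <- matrix(rnorm(5 * 8), 5)
  D <- correlation_distance(S)
  for (i in 1:5) for (j in 1:5) {
    expected <- if (i == j) 0 else 1 - cor(S[i, ], S[j, ])
    expect_lt(abs(D[i, j] - expected), 1e-12)
  }
  expect_identical(D, t(D))
  Sbad <- S; Sbad[3, ] <- 7
  expect_error(correlation_distance(Sbad), "subject.*3")
})

test_that("ward clustering recovers well-separated planted groups", {
  # groups separated along the first component: the planted structure a
  # PCA score matrix carries (a uniform all-component shift would be
  # invisible to row-wise correlation distance)
  set.seed(4)
  S <- cbind(c(rnorm(20, -6), rnorm(15, 6)), matrix(rnorm(35 * 4), 35))
  planted <- rep(1:2, c(20, 15))
  wc <- ward_cluster(correlation_distance(S), 2)
  expect_equal(adjusted_rand(wc$labels, planted), 1)
  expect_true(all(diff(wc$height) >= -1e-10))
})

test_that("cutting at k = n gives singletons", {
  set.seed(5)
  S <- matrix(rnorm(6 * 4), 6)
  wc <- ward_cluster(correlation_distance(S), 6)
  expect_identical(sort(unique(wc$labels)), 1:6)
})

test_that("ward merge sequences match a from-scratch ESS agglomerator", {
  # on squared Euclidean input, Lance-Williams ward.D reproduces classic
  # Ward; the oracle recomputes every merge cost from the raw points
  set.seed(6)
  for (rep in 1:5) {
    P <- matrix(rnorm(8 * 3), 8)
    D2 <- as.matrix(dist(P))^2
    wc <- ward_cluster(D2, 2)
    ours <- t(apply(wc$merge, 1, sort))
    expect_identical(ours, oracle_ward_merges(P))
  }
})

test_that("invalid distance matrices are rejected", {
  D <- matrix(c(0, 1, 2, 0), 2)
  expect_error(ward_cluster(D, 2), "symmetric")
  D2 <- matrix(c(0.5, 1, 1, 0), 2)
  expect_error(ward_cluster(D2, 2), "zero diagonal|symmetric")
})

test_that("calinski_harabasz reproduces the hand-computed value 200", {
  S <- matrix(c(0, 1, 10, 11), 4)
  labels <- c(1, 1, 2, 2)
  # B = 100, W = 1, n = 4, k = 2 -> (100/1)/(1/2) = 200
  expect_equal(calinski_harabasz(S, labels), 200)
})

test_that("calinski_harabasz is invariant to label permutations", {
  set.seed(7)
  S <- matrix(rnorm(30 * 4), 30)
  labels <- sample(1:3, 30, replace = TRUE)
  expect_equal(calinski_harabasz(S, labels),
               calinski_harabasz(S, c(2, 3, 1)[labels]))
  expect_error(calinski_harabasz(matrix(c(1, 1, 5, 5), 4), c(1, 1, 2, 2)),
               "degenerate")
})

test_that("select_k chooses 2 on planted two-cluster data", {
  hits <- vapply(1:5, function(s) {
    set.seed(200 + s)
    S <- cbind(c(rnorm(30, -4), rnorm(30, 4)), matrix(rnorm(60 * 5), 60))
    select_k(S, k_range = 2:6)$k
  }, integer(1))
  expect_true(all(hits == 2L))
})

test_that("kmeans_cluster behaves as a seeded best-of-n Lloyd", {
  set.seed(8)
  S <- rbind(matrix(rnorm(25 * 3), 25), matrix(rnorm(25 * 3, 5), 25))
  expect_identical(kmeans_cluster(S, 1, seed = 1)$labels, rep(1L, 50))
  km <- kmeans_cluster(S, 2, seed = 9, n_init = 20)
  expect_equal(adjusted_rand(km$labels, rep(1:2, each = 25)), 1)
  # reproducible under the same seed
  expect_identical(km$labels, kmeans_cluster(S, 2, seed = 9, n_init = 20)$labels)
  # best-of-n objective cannot exceed a single-init objective
  km1 <- kmeans_cluster(S, 3, seed = 10, n_init = 1)
  km50 <- kmeans_cluster(S, 3, seed = 10, n_init = 50)
  expect_lte(km50$tot_withinss, km1$tot_withinss + 1e-9)
  expect_true(all(km50$objectives >= km50$tot_withinss - 1e-9))
  expect_error(kmeans_cluster(S, 51, seed = 1), "exceed")
})

test_that("kappa_agreement aligns labels and applies the chance correction", {
  a <- rep(1:2, each = 25)
  expect_equal(kappa_agreement(a, a), 1)
  expect_equal(kappa_agreement(a, 3 - a), 1)  # swapped labels realign
  # confusion [[40,10],[10,40]]: p_o = 0.8, p_e = 0.5 -> kappa = 0.6
  truth <- rep(1:2, each = 50)
  other <- c(rep(1, 40), rep(2, 10), rep(1, 10), rep(2, 40))
  expect_equal(kappa_agreement(truth, other), 0.6)
  expect_equal(kappa_agreement(truth, rep(1, 100)), 0)
  expect_error(kappa_agreement(1:4, 1:5), "length")
})

test_that("adjusted_rand agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(10)
  for (i in 1:10) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("clustering outputs are invariant to subject ordering", {
  set.seed(11)
  S <- rbind(matrix(rnorm(20 * 5), 20), matrix(rnorm(20 * 5, 4), 20))
  perm <- sample(40)
  wc <- ward_cluster(correlation_distance(S), 2)
  wc_p <- ward_cluster(correlation_distance(S[perm, ]), 2)
  expect_equal(adjusted_rand(wc$labels[perm], wc_p$labels), 1)
  expect_equal(calinski_harabasz(S, wc$labels),
               calinski_harabasz(S[perm, ], wc$labels[perm]))
})
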