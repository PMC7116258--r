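make_covars <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    age = rnorm(n, 60, 9),
    sex = sample(c("male", "female"), n, replace = TRUE),
    education = rnorm(n, 15, 3),
    race = sample(c("white", "other"), n, replace = TRUE, prob = c(0.9, 0.1)),
    site = sample(paste0("site", 1:4), n, replace = TRUE)
  )
}

test_that("residualization removes exact linear confound structure", {
  cov <- make_covars(50)
  res <- residualize(matrix(2 * cov$age), cov)
  expect_lt(max(abs(res)), 1e-10)
})

test_that("a centred feature orthogonal to the design is left unchanged", {
  cov <- make_covars(60, seed = 2)
  X <- model.matrix(~ ., cov)
  # project random noise off the design: orthogonal + centred by construction
  set.seed(3)
  y <- rnorm(60)
  y_perp <- y - X %*% solve(crossprod(X), crossprod(X, y))
  res <- residualize(matrix(y_perp), cov)
  expect_lt(max(abs(res - y_perp)), 1e-10)
})

test_that("residuals match the explicit normal-equation oracle", {
  cov <- make_covars(50, seed = 4)
  set.seed(5)
  vals <- matrix(rnorm(50 * 20), 50)
  ours <- residualize(vals, cov)
  X <- model.matrix(~ ., cov)
  expect_lt(max(abs(ours - oracle_residuals(vals, X))), 1e-8)
  # residuals orthogonal to every design column
  expect_lt(max(abs(crossprod(X, ours))), 1e-8)
})

test_that("rank-deficient confound designs are refused with the column named", {
  cov <- make_covars(40, seed = 6)
  cov$age2 <- cov$age  # exact duplicate
  expect_error(residualize(matrix(rnorm(40)), cov), "collinear.*age2")
})

test_that("PD-fitted coefficients transfer to held-out subjects", {
  cov <- make_covars(80, seed = 7)
  set.seed(8)
  vals <- matrix(rnorm(80 * 5), 80)
  fit <- residualize(vals[1:50, ], cov[1:50, ])
  applied <- residualize_apply(fit, vals[51:80, ], cov[51:80, ])
  X <- model.matrix(~ ., cov)
  beta <- solve(crossprod(X[1:50, ]), crossprod(X[1:50, ], vals[1:50, ]))
  expect_lt(max(abs(applied - (vals[51:80, ] - X[51:80, ] %*% beta))), 1e-8)
})

test_that("spearman_rho handles monotone and tied data", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(unname(spearman_rho(x, exp(x))["rho"]), 1)
  expect_equal(unname(spearman_rho(x, -x^3)["rho"]), -1)
  expect_equal(unname(spearman_rho(x, exp(x))["p"]), 0)
  # tie-heavy example against the rank-then-Pearson oracle
  x2 <- c(1, 2, 2, 4); y2 <- c(3, 1, 4, 4)
  expect_equal(unname(spearman_rho(x2, y2)), unname(oracle_spearman(x2, y2)),
               tolerance = 1e-12)
  set.seed(9)
  for (i in 1:20) {
    a <- sample(1:6, 12, replace = TRUE)
    b <- sample(1:6, 12, replace = TRUE)
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    expect_equal(unname(spearman_rho(a, b)), unname(oracle_spearman(a, b)),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 10), 1:10), "constant")
  expect_error(spearman_rho(1:3, 3:1), "at least 4")
})

test_that("spearman p agrees with cor.test's t approximation", {
  set.seed(10)
  x <- rnorm(40); y <- 0.3 * x + rnorm(40)
  ours <- spearman_rho(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(unname(ours["rho"]), unname(ref$estimate), tolerance = 1e-12)
  expect_equal(unname(ours["p"]), ref$p.value, tolerance = 1e-10)
})

test_that("a noiseless monotone voxel is selected for its score and the union", {
  set.seed(11)
  n <- 60
  scores <- as.data.frame(matrix(rnorm(n * 6), n))
  names(scores) <- score_cols
  X <- matrix(rnorm(n * 30), n)
  X[, 7] <- scores$updrs3^3  # strictly monotone in UPDRS-III
  fm <- select_features(X, scores, alpha = 0.01)
  expect_true(fm$masks[7, "updrs3"])
  expect_true(fm$union[7])
})

test_that("the union mask is the logical OR of the per-score masks", {
  set.seed(12)
  n <- 80
  scores <- as.data.frame(matrix(rnorm(n * 6), n))
  names(scores) <- score_cols
  X <- matrix(rnorm(n * 200), n)
  fm <- select_features(X, scores, alpha = 0.2)
  oracle_union <- Reduce(`|`, lapply(seq_len(6), function(k) fm$masks[, k]))
  expect_identical(fm$union, oracle_union)
  expect_identical(fm$counts[["union"]], sum(oracle_union))
  expect_gte(fm$counts[["union"]], max(fm$counts[score_cols]))
  expect_lte(fm$counts[["union"]], sum(fm$counts[score_cols]))
})

test_that("selection is invariant to monotone transforms of a score", {
  set.seed(13)
  n <- 50
  X <- matrix(rnorm(n * 40), n)
  scores <- as.data.frame(matrix(rnorm(n * 6), n))
  names(scores) <- score_cols
  fm1 <- select_features(X, scores, alpha = 0.05)
  scores2 <- scores
  scores2$updrs1 <- exp(scores2$updrs1)
  scores2$pigd <- qlogis(plogis(scores2$pigd))^3
  fm2 <- select_features(X, scores2, alpha = 0.05)
  expect_identical(fm1$masks, fm2$masks)
})

test_that("scores with too few complete cases are refused", {
  set.seed(14)
  n <- 30
  scores <- as.data.frame(matrix(rnorm(n * 6), n))
  names(scores) <- score_cols
  scores$tremor[10:30] <- NA
  expect_error(select_features(matrix(rnorm(n * 5), n), scores),
               "tremor.*complete cases")
})

test_that("null selection rate is near alpha (single-seed check)", {
  set.seed(15)
  n <- 300
  X <- matrix(rnorm(n * 2000), n)
  scores <- as.data.frame(matrix(rnorm(n * 6), n))
  names(scores) <- score_cols
  fm <- select_features(X, scores, alpha = 0.01)
  rate <- mean(fm$masks)
  ci <- qbinom(c(0.005, 0.995), 2000 * 6, 0.01) / (2000 * 6)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("score residualization removes confound-driven selections", {
  set.seed(17)
  n <- 200
  cov <- make_covars(n, seed = 18)
  # voxels and scores both driven by age: screening residualized voxels
  # against raw scores finds nothing (the shared direction is projected
  # out of the voxels), and the score-residualized screen agrees
  X <- matrix(rnorm(n * 50), n) + 0.5 * cov$age
  scores <- as.data.frame(matrix(rnorm(n * 6), n) + 0.2 * cov$age)
  names(scores) <- score_cols
  R <- residualize(X, cov)
  fm_raw <- select_features(R, scores, alpha = 0.01)
  fm_res <- select_features(R, scores, alpha = 0.01, covariates = cov)
  expect_lte(fm_raw$counts[["union"]], 5)
  expect_lte(fm_res$counts[["union"]], 5)
})

test_that("per-score missingness uses complete cases per score only", {
  set.seed(16)
  n <- 60
  X <- matrix(rnorm(n * 20), n)
  scores <- as.data.frame(matrix(rnorm(n * 6), n))
  names(scores) <- score_cols
  scores$updrs2[1:20] <- NA
  fm <- select_features(X, scores, alpha = 0.05)
  expect_identical(unname(fm$n_complete["updrs2"]), 40L)
  expect_identical(unname(fm$n_complete["updrs1"]), 60L)
  # updrs2 mask must equal a selection run on its complete cases alone
  fm_sub <- select_features(X[21:60, ], scores[21:60, ], alpha = 0.05)
  expect_identical(fm$masks[, "updrs2"], fm_sub$masks[, "updrs2"])
})
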