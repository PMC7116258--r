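test_that("bh_fdr reproduces the hand step-up example", {
  # i* = 4 because p_(4) = 0.041 <= (4/4) * 0.05, so all four reject
  expect_identical(bh_fdr(c(0.001, 0.008, 0.039, 0.041), q = 0.05),
                   rep(TRUE, 4))
  expect_identical(bh_fdr(rep(1, 10), q = 0.05), rep(FALSE, 10))
  expect_error(bh_fdr(c(0.1, 1.2), 0.05), "0, 1")
})

test_that("bh_fdr matches a brute-force threshold-scan oracle", {
  set.seed(1)
  for (i in 1:200) {
    m <- sample(3:40, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- sample(c(0.005, 0.01, 0.05, 0.1), 1)
    expect_identical(bh_fdr(p, q), oracle_bh(p, q))
  }
})

test_that("bh_fdr rejections are monotone in q", {
  set.seed(2)
  p <- runif(500)^2
  r_strict <- bh_fdr(p, 0.005)
  r_loose <- bh_fdr(p, 0.05)
  expect_true(all(r_loose[r_strict]))
})

test_that("identical groups give zero t and an empty significance mask", {
  set.seed(3)
  m <- matrix(rnorm(10 * 50), 10)
  cm <- voxelwise_group_ttest(m, m, q = 0.05)
  expect_lt(max(abs(cm$t)), 1e-12)
  expect_false(any(cm$mask))
})

test_that("voxel t matches the textbook pooled two-sample formula", {
  set.seed(4)
  a <- matrix(rnorm(12), 12); b <- matrix(rnorm(15, 0.5), 15)
  cm <- voxelwise_group_ttest(a, b, q = 0.05)
  na <- 12; nb <- 15
  sp <- sqrt(((na - 1) * var(a[, 1]) + (nb - 1) * var(b[, 1])) / (na + nb - 2))
  t_oracle <- (mean(a[, 1]) - mean(b[, 1])) / (sp * sqrt(1 / na + 1 / nb))
  expect_lt(abs(cm$t[1] - t_oracle), 1e-10)
  expect_equal(cm$p[1], 2 * pt(-abs(t_oracle), na + nb - 2), tolerance = 1e-12)
  ref <- t.test(a[, 1], b[, 1], var.equal = TRUE)
  expect_equal(cm$p[1], ref$p.value, tolerance = 1e-12)
})

test_that("planted voxel shifts are detected with FDR control", {
  hits <- integer(0); fps <- integer(0)
  for (s in 1:5) {
    set.seed(400 + s)
    n <- 60; v <- 400
    a <- matrix(rnorm(n * v), n)
    b <- matrix(rnorm(n * v), n)
    b[, 1:50] <- b[, 1:50] + 1.5
    cm <- voxelwise_group_ttest(a, b, q = 0.005)
    hits <- c(hits, sum(cm$mask[1:50]))
    fps <- c(fps, sum(cm$mask[51:v]))
  }
  expect_true(all(hits >= 45))
  expect_lte(mean(fps), 2)  # 350 null voxels at q = 0.005
})

test_that("zero-variance voxels become NA and leave the FDR family", {
  set.seed(5)
  a <- matrix(rnorm(20), 10); b <- matrix(rnorm(20), 10)
  a[, 2] <- 1; b[, 2] <- 1
  cm <- voxelwise_group_ttest(a, b, q = 0.05)
  expect_true(is.na(cm$t[2]))
  expect_false(cm$mask[2])
})

test_that("covariate residualization adjusts the degrees of freedom", {
  set.seed(6)
  n <- 30
  cov <- data.frame(age = rnorm(2 * n), sex = sample(c("m", "f"), 2 * n, TRUE))
  a <- matrix(rnorm(n * 3), n); b <- matrix(rnorm(n * 3), n)
  cm <- voxelwise_group_ttest(a, b, covariates = cov, q = 0.05)
  expect_identical(cm$df, as.integer(2 * n - 2 - 2))
})

test_that("baseline_comparison reproduces the hand chi-square value", {
  # 2x2 table [[20,10],[10,20]]: chi2 = n(ad-bc)^2/(r1 r2 c1 c2) = 20/3
  cohort <- data.frame(
    phenotype = rep(c("x", "y", "x", "y"), c(20, 10, 10, 20)))
  labels <- rep(1:2, each = 30)
  out <- baseline_comparison(cohort, labels, categorical = "phenotype",
                             confounds = character())
  expect_equal(out$statistic, 20 / 3, tolerance = 1e-12)
  expect_identical(out$df, 1L)
})

test_that("a variable identical across groups is not flagged", {
  set.seed(7)
  cohort <- data.frame(v = rep(c(1, 2, 3), 20))
  labels <- rep(1:2, 30)
  out <- baseline_comparison(cohort, labels, continuous = "v",
                             confounds = character())
  expect_lt(abs(out$statistic), 1e-8)
  expect_false(out$significant)
})

test_that("a planted 1 SD group difference is flagged after FDR", {
  flagged <- vapply(1:5, function(s) {
    set.seed(500 + s)
    n <- 150
    cohort <- as.data.frame(matrix(rnorm(2 * n * 20), 2 * n))
    names(cohort) <- paste0("v", 1:20)
    labels <- rep(1:2, each = n)
    cohort$v7 <- cohort$v7 + (labels == 2)  # 1 SD shift
    out <- baseline_comparison(cohort, labels,
                               continuous = paste0("v", 1:20),
                               confounds = character())
    out$significant[out$variable == "v7"] &&
      sum(out$significant) <= 3
  }, logical(1))
  expect_true(all(flagged))
})

test_that("empty expected chi-square cells are refused", {
  cohort <- data.frame(cat = rep("only_level", 40))
  cohort$cat[1:20] <- "a"
  labels <- rep(1:2, each = 20)
  cohort$cat <- factor(cohort$cat, levels = c("a", "only_level", "ghost"))
  expect_error(baseline_comparison(cohort, labels, categorical = "cat",
                                   confounds = character()),
               "merge categories")
})

test_that("classifier metrics follow the confusion-matrix arithmetic", {
  set.seed(8)
  n <- 60; d <- 8
  X <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d, 3), n))
  y <- rep(c(1, 2), each = n)
  m <- crossval_svm(X, y, folds = 10, seed = 4)
  cf <- m$confusion
  tp <- cf["1", "1"]; fn <- cf["1", "2"]; tn <- cf["2", "2"]; fp <- cf["2", "1"]
  expect_equal(m$accuracy, (tp + tn) / (2 * n))
  expect_equal(m$sensitivity, tp / (tp + fn))
  expect_equal(m$specificity, tn / (tn + fp))
  expect_equal(sum(cf), 2 * n)
})

test_that("a separable problem is classified nearly perfectly", {
  set.seed(9)
  n <- 60; d <- 10
  X <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d, 3), n))
  y <- rep(c(1, 2), each = n)
  m <- crossval_svm(X, y, folds = 10, seed = 4)
  expect_gte(m$accuracy, 0.95)
  expect_gte(m$auc, 0.98)
})

test_that("AUC matches the pROC reference on pooled decision values", {
  skip_if_not_installed("pROC")
  set.seed(10)
  X <- rbind(matrix(rnorm(200), 40), matrix(rnorm(200, 0.8), 40))
  y <- rep(c(1, 2), each = 40)
  m <- crossval_svm(X, y, folds = 5, seed = 2)
  ref <- pROC::auc(pROC::roc(response = m$predictions$truth == m$positive,
                             predictor = m$predictions$decision,
                             direction = "<", quiet = TRUE))
  expect_equal(m$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("permuted labels give chance-level accuracy", {
  set.seed(11)
  n <- 50; d <- 6
  X <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d, 3), n))
  y <- sample(rep(c(1, 2), each = n))
  m <- crossval_svm(X, y, folds = 10, seed = 3)
  band <- qbinom(c(0.025, 0.975), 2 * n, 0.5) / (2 * n)
  expect_gte(m$accuracy, band[1])
  expect_lte(m$accuracy, band[2] + 0.05)  # majority-vote drift upper slack
})

test_that("fold standardization never sees held-out subjects", {
  set.seed(12)
  n <- 40; d <- 4
  X <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d, 2), n))
  y <- rep(c(1, 2), each = n)
  m_clean <- crossval_svm(X, y, folds = 5, seed = 7)
  # plant a gigantic outlier in one subject; folds are seed-determined
  out_subject <- which(m_clean$predictions$fold == 3)[1]
  X2 <- X
  X2[out_subject, ] <- 1e6
  m_dirty <- crossval_svm(X2, y, folds = 5, seed = 7)
  # training statistics of the fold holding that subject out are untouched
  expect_equal(m_clean$fold_scaling[[3]], m_dirty$fold_scaling[[3]],
               tolerance = 1e-12)
  # ...while folds that train on it shift
  expect_gt(max(abs(m_dirty$fold_scaling[[1]]$mean -
                      m_clean$fold_scaling[[1]]$mean)), 1)
})

test_that("metrics are invariant to pre-pipeline feature scaling", {
  set.seed(13)
  n <- 40; d <- 5
  X <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d, 2), n))
  y <- rep(c(1, 2), each = n)
  m1 <- crossval_svm(X, y, folds = 5, seed = 9)
  m2 <- crossval_svm(sweep(X, 2, c(10, 0.1, 3, 100, 0.5), "*"), y,
                     folds = 5, seed = 9)
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$auc, m2$auc, tolerance = 1e-8)
})

test_that("nested re-selection classifies planted biotypes without leakage", {
  co <- simulate_cohort(tiny_config(seed = 20, effect_size = 1))
  pd <- co$cohort$group == "PD"
  nested <- crossval_svm_nested(co$maps[pd, ], co$cohort[pd, score_cols],
                                co$cohort[pd, confound_cols],
                                co$truth$biotype, folds = 5, seed = 21)
  expect_gte(nested$accuracy, 0.8)
  expect_true(all(nested$fold_selected > 0))
  expect_true(nested$nested)
})

test_that("stratification failures are reported", {
  X <- matrix(rnorm(26 * 3), 26)
  y <- rep(c(1, 2), c(21, 5))
  expect_error(crossval_svm(X, y, folds = 10), "at least")
})
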