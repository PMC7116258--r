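# Biotype validation: voxelwise biotype-vs-control contrasts under FDR
# control, baseline clinical comparison tables, and a cross-validated
# RBF-kernel SVM that diagnoses biotype from neuroanatomic features.

#' Benjamini-Hochberg rejection mask
#'
#' Step-up FDR control: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' rejects all hypotheses up to `i* = max{i : p_(i) <= (i/m) q}`.
#' Implemented through `stats::p.adjust(..., "BH")`, whose adjusted
#' p-values fall at or below `q` exactly on that step-up set. `NA`
#' p-values are never rejected and do not count toward `m`.
#'
#' @param pvals numeric p-values in \[0, 1\] (NAs allowed).
#' @param q FDR level in (0, 1).
#' @return logical rejection mask in input order.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  q <- .check_prob(q, "q")
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(FALSE, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH") <= q
  out
}

#' Voxelwise two-sample contrast with FDR control
#'
#' Per voxel: pooled-variance two-sample t-test between the two groups
#' on covariate-residualized values (one residualization fitted on the
#' combined sample; the group factor is not part of the confound
#' design), with `df = n_a + n_b - 2 - q_cov` where `q_cov` is the
#' number of non-intercept confound columns. BH-FDR is applied across
#' all testable voxels at level `q`. Voxels with zero pooled variance
#' are returned as NA and excluded from the FDR family.
#'
#' @param maps_a,maps_b subjects x voxels matrices for the two groups.
#' @param covariates optional data.frame with `nrow(maps_a) +
#'   nrow(maps_b)` rows (group a first).
#' @param q FDR level (default 0.005, the map-level convention).
#' @return object of class `contrast_map`: `t`, `p`, logical `mask`,
#'   `q`, `df`, `n_a`, `n_b`.
#' @export
voxelwise_group_ttest <- function(maps_a, maps_b, covariates = NULL, q = 0.005) {
  maps_a <- as.matrix(maps_a); maps_b <- as.matrix(maps_b)
  if (ncol(maps_a) != ncol(maps_b)) stop("voxel grids differ", call. = FALSE)
  n_a <- nrow(maps_a); n_b <- nrow(maps_b)
  if (n_a < 2L || n_b < 2L) stop("need >= 2 subjects per group", call. = FALSE)
  q_cov <- 0L
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n_a + n_b) {
      stop("`covariates` must cover both groups, group a first", call. = FALSE)
    }
    res <- residualize(rbind(maps_a, maps_b), covariates)
    q_cov <- nrow(as.matrix(attr(res, "coefficients"))) - 1L
    maps_a <- res[seq_len(n_a), , drop = FALSE]
    maps_b <- res[n_a + seq_len(n_b), , drop = FALSE]
  }
  mean_a <- colMeans(maps_a); mean_b <- colMeans(maps_b)
  ss_a <- colSums(sweep(maps_a, 2, mean_a)^2)
  ss_b <- colSums(sweep(maps_b, 2, mean_b)^2)
  df <- n_a + n_b - 2L - q_cov
  sp2 <- (ss_a + ss_b) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  tval <- ifelse(se > 0, (mean_a - mean_b) / se, NA_real_)
  pval <- 2 * stats::pt(-abs(tval), df = df)
  mask <- bh_fdr(pval, q)
  structure(list(t = tval, p = pval, mask = mask, q = q, df = df,
                 n_a = n_a, n_b = n_b),
            class = "contrast_map")
}

#' Baseline group comparison table
#'
#' Continuous variables are compared with a pooled-variance two-sample
#' t-test after confound residualization (each variable's own name is
#' dropped from its confound set); categorical variables with a Pearson
#' chi-square test (no continuity correction). P-values are BH-adjusted
#' across the whole variable family at level `q`. Per-variable complete
#' cases are used throughout.
#'
#' @param cohort data.frame with one row per subject.
#' @param labels two-level grouping over the rows of `cohort`.
#' @param continuous,categorical character vectors of column names.
#' @param confounds confound column names for the continuous tests.
#' @param q FDR level across the variable family.
#' @return data.frame: variable, type, per-group `mean (SD)` or counts,
#'   statistic, df, p, p_adj, significant.
#' @export
baseline_comparison <- function(cohort, labels,
                                continuous = character(),
                                categorical = character(),
                                confounds = c("age", "sex", "education",
                                              "race", "site"),
                                q = 0.05) {
  stopifnot(nrow(cohort) == length(labels))
  glev <- sort(unique(labels))
  if (length(glev) != 2L) stop("`labels` must define exactly 2 groups",
                               call. = FALSE)
  rows <- list()
  for (v in continuous) {
    ok <- is.finite(cohort[[v]])
    conf <- setdiff(intersect(confounds, names(cohort)), v)
    x <- cohort[[v]][ok]
    if (length(conf)) {
      x <- as.vector(residualize(matrix(x), cohort[ok, conf, drop = FALSE]))
    }
    g <- labels[ok]
    tt <- stats::t.test(x[g == glev[1]], x[g == glev[2]], var.equal = TRUE)
    fmt <- function(vals) sprintf("%.2f (%.2f)", mean(vals), stats::sd(vals))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "continuous",
      group1 = fmt(cohort[[v]][ok][g == glev[1]]),
      group2 = fmt(cohort[[v]][ok][g == glev[2]]),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    ok <- !is.na(cohort[[v]])
    tab <- table(labels[ok], cohort[[v]][ok])
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0)) {
      stop(sprintf("variable `%s` has an empty expected cell; merge categories",
                   v), call. = FALSE)
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    fmt <- function(r) paste(sprintf("%s:%d", colnames(tab), tab[r, ]),
                             collapse = " ")
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "categorical",
      group1 = fmt(1L), group2 = fmt(2L),
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p = ct$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj <= q
  out
}

#' Cross-validated RBF-kernel SVM biotype classifier
#'
#' Stratified k-fold cross-validation. Within each fold the feature
#' standardization (training means/SDs) and the SVM are fitted on the
#' training split only; held-out subjects are standardized with the
#' training statistics and predicted. Metrics come from the pooled
#' out-of-fold predictions; AUC is the rank statistic of the pooled
#' decision values oriented toward the positive class.
#'
#' @param features subjects x features matrix.
#' @param labels two-level class vector.
#' @param folds number of CV folds (default 10).
#' @param seed seed for the fold assignment.
#' @param positive positive class for sensitivity; default the minority
#'   class (the smaller biotype).
#' @param cost SVM soft-margin cost (default 1).
#' @param gamma RBF width; default `1 / n_features` on standardized
#'   features.
#' @return object of class `classifier_metrics`: accuracy, sensitivity,
#'   specificity, auc, pooled `confusion`, per-fold confusions,
#'   `predictions` data.frame, the fold standardization statistics, and
#'   the run metadata (folds, seed, cost, gamma, positive class).
#' @export
crossval_svm <- function(features, labels, folds = 10L, seed = 1L,
                         positive = NULL, cost = 1, gamma = NULL) {
  X <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("`labels` must have exactly 2 classes",
                             call. = FALSE)
  folds <- .check_count(folds, "folds")
  if (min(table(y)) < folds) {
    stop("each class needs at least `folds` members for stratified CV",
         call. = FALSE)
  }
  if (is.null(positive)) positive <- names(which.min(table(y)))
  positive <- as.character(positive)
  if (!positive %in% levels(y)) stop("`positive` is not a class label",
                                     call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(X)

  fold_id <- integer(length(y))
  .with_seed(seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })

  pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
  dval <- numeric(length(y))
  fold_conf <- vector("list", folds)
  fold_scaling <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Zte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    fit <- e1071::svm(Ztr, y[tr], kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
    pr <- stats::predict(fit, Zte, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # orient decision values so larger favours the positive class
    lev_pair <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]]
    if (lev_pair[1] != positive) dv <- -dv
    pred[!tr] <- pr
    dval[!tr] <- dv
    fold_conf[[f]] <- table(truth = y[!tr], pred = pr)
    fold_scaling[[f]] <- list(mean = mu, sd = sdv)
  }

  is_pos <- y == positive
  tp <- sum(pred == positive & is_pos)
  tn <- sum(pred != positive & !is_pos)
  fp <- sum(pred == positive & !is_pos)
  fn <- sum(pred != positive & is_pos)
  structure(list(
    accuracy = (tp + tn) / length(y),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    auc = .rank_auc(dval, is_pos),
    confusion = table(truth = y, pred = pred),
    fold_confusions = fold_conf,
    predictions = data.frame(truth = y, pred = pred, decision = dval,
                             fold = fold_id),
    fold_scaling = fold_scaling,
    folds = folds, seed = seed, cost = cost, gamma = gamma,
    positive = positive
  ), class = "classifier_metrics")
}

#' Nested-selection cross-validated SVM
#'
#' Variant of [crossval_svm()] in which confound residualization *and*
#' the Spearman voxel screen are re-fitted inside every training fold,
#' so no information from held-out subjects reaches feature selection.
#' The default pipeline deliberately selects on the full sample before
#' CV (replicating the design it implements); this function quantifies
#' how much of the reported performance that leakage buys.
#'
#' @param values subjects x voxels matrix (unresidualized).
#' @param scores data.frame of the six clinical scores for the same
#'   subjects.
#' @param covariates confound data.frame for the same subjects.
#' @param labels two-level class vector.
#' @param alpha selection level inside each fold.
#' @inheritParams crossval_svm
#' @return a `classifier_metrics` object; `fold_selected` records the
#'   union-mask size per fold.
#' @export
crossval_svm_nested <- function(values, scores, covariates, labels,
                                folds = 10L, seed = 1L, alpha = 0.01,
                                positive = NULL, cost = 1, gamma = NULL) {
  X <- as.matrix(values)
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("`labels` must have exactly 2 classes",
                             call. = FALSE)
  folds <- .check_count(folds, "folds")
  if (min(table(y)) < folds) {
    stop("each class needs at least `folds` members for stratified CV",
         call. = FALSE)
  }
  if (is.null(positive)) positive <- names(which.min(table(y)))
  positive <- as.character(positive)

  fold_id <- integer(length(y))
  .with_seed(seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })

  pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
  dval <- numeric(length(y))
  fold_selected <- integer(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    res_tr <- residualize(X[tr, , drop = FALSE],
                          as.data.frame(covariates)[tr, , drop = FALSE])
    fm <- select_features(res_tr,
                          as.data.frame(scores)[tr, , drop = FALSE],
                          alpha = alpha)
    cols <- fm$union
    if (sum(cols) < 2L) stop(sprintf(
      "fold %d selected %d voxels; cannot train", f, sum(cols)), call. = FALSE)
    fold_selected[f] <- sum(cols)
    res_te <- residualize_apply(res_tr, X[!tr, , drop = FALSE],
                                as.data.frame(covariates)[!tr, , drop = FALSE])
    Ztr <- res_tr[, cols, drop = FALSE]
    Zte <- res_te[, cols, drop = FALSE]
    mu <- colMeans(Ztr)
    sdv <- apply(Ztr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Ztr <- sweep(sweep(Ztr, 2, mu), 2, sdv, "/")
    Zte <- sweep(sweep(Zte, 2, mu), 2, sdv, "/")
    g <- if (is.null(gamma)) 1 / ncol(Ztr) else gamma
    fit <- e1071::svm(Ztr, y[tr], kernel = "radial", cost = cost,
                      gamma = g, scale = FALSE)
    pr <- stats::predict(fit, Zte, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    lev_pair <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]]
    if (lev_pair[1] != positive) dv <- -dv
    pred[!tr] <- pr
    dval[!tr] <- dv
  }

  is_pos <- y == positive
  tp <- sum(pred == positive & is_pos)
  tn <- sum(pred != positive & !is_pos)
  fp <- sum(pred == positive & !is_pos)
  fn <- sum(pred != positive & is_pos)
  structure(list(
    accuracy = (tp + tn) / length(y),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    auc = .rank_auc(dval, is_pos),
    confusion = table(truth = y, pred = pred),
    fold_selected = fold_selected,
    predictions = data.frame(truth = y, pred = pred, decision = dval,
                             fold = fold_id),
    folds = folds, seed = seed, cost = cost, gamma = gamma,
    positive = positive, nested = TRUE
  ), class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf(
    "10-fold-style CV SVM: accuracy %.1f%%, sensitivity %.2f, specificity %.2f, AUC %.2f (positive class: %s)\n",
    100 * x$accuracy, x$sensitivity, x$specificity, x$auc, x$positive))
  invisible(x)
}
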