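# Confound residualization and Spearman voxel screening.
#
# Selection is rank-based and deliberately uncorrected for multiple
# comparisons (alpha = 0.01 per score, union across scores); the
# screen's purpose is to feed clustering a permissive symptom-linked
# feature set, not to make voxelwise inference.

#' Residualize features against confounds
#'
#' Ordinary-least-squares residuals of every feature column from a
#' model with intercept plus the supplied covariates (continuous terms
#' entered linearly, factors as dummy columns). The fitted coefficients
#' are attached so that held-out subjects (e.g. controls, when the model
#' was fitted within patients) can be residualized with the same
#' coefficients via [residualize_apply()].
#'
#' @param values numeric subjects x features matrix.
#' @param covariates data.frame of covariates for the same subjects, in
#'   the same row order. All columns are used.
#' @return residual matrix (same shape as `values`) with attributes
#'   `coefficients` and `terms` recording the fitted model.
#' @export
residualize <- function(values, covariates) {
  values <- as.matrix(values)
  covariates <- as.data.frame(covariates)
  if (nrow(values) != nrow(covariates)) {
    stop("`values` and `covariates` must have the same number of rows",
         call. = FALSE)
  }
  if (anyNA(covariates)) stop("covariates contain missing values", call. = FALSE)
  mf <- stats::model.frame(~ ., data = covariates)
  X <- stats::model.matrix(~ ., data = mf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("confound design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qx, values)
  res <- values - X %*% coef
  attr(res, "coefficients") <- coef
  attr(res, "xlevels") <- lapply(
    Filter(function(x) is.factor(x) || is.character(x), covariates),
    function(x) levels(as.factor(x)))
  attr(res, "covariate_names") <- names(covariates)
  res
}

#' @rdname residualize
#' @param fit a residual matrix returned by [residualize()] (carries the
#'   fitted coefficients).
#' @export
residualize_apply <- function(fit, values, covariates) {
  coef <- attr(fit, "coefficients")
  if (is.null(coef)) stop("`fit` does not carry residualization coefficients",
                          call. = FALSE)
  values <- as.matrix(values)
  covariates <- as.data.frame(covariates)
  for (nm in names(attr(fit, "xlevels"))) {
    covariates[[nm]] <- factor(covariates[[nm]], levels = attr(fit, "xlevels")[[nm]])
  }
  X <- stats::model.matrix(~ ., data = covariates)
  X <- X[, rownames(coef), drop = FALSE]
  values - X %*% coef
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties get average
#' ranks); the two-sided p-value uses the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' which is accurate in the n of a few hundred regime this screen runs
#' in. For perfectly monotone data (|rho| = 1) the p-value is 0.
#'
#' @param x,y numeric vectors, length >= 4, neither constant.
#' @return named numeric vector `c(rho =, p =)`.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- .spearman_p(rho, n)
  c(rho = rho, p = p)
}

.spearman_p <- function(rho, n) {
  ifelse(abs(rho) >= 1, 0,
         2 * stats::pt(-abs(rho) * sqrt((n - 2) / (1 - rho^2)), df = n - 2))
}

# Vectorized screen of all columns of X against one score vector.
# Returns the two-sided t-approximation p-value per column.
.spearman_screen <- function(X, y) {
  n <- length(y)
  Xr <- apply(X, 2, rank)
  rho <- as.vector(stats::cor(Xr, rank(y)))
  .spearman_p(rho, n)
}

#' Select symptom-correlated voxels
#'
#' For each of the six baseline clinical scores, marks the voxels whose
#' residualized values have a two-sided Spearman p-value below `alpha`
#' (uncorrected by default); the union mask pools voxels correlated
#' with at least one score. Subjects missing a score are dropped for
#' that score only (complete case per score).
#'
#' @param residualized subjects x voxels matrix of confound-residualized
#'   values (see [residualize()]).
#' @param scores data.frame or matrix with the six score columns, same
#'   subjects and row order as `residualized`. Missing values allowed.
#' @param alpha per-test two-sided significance level, in (0, 1).
#' @param adjust `"none"` (default, mirroring an uncorrected screen) or
#'   `"BH"` to select on Benjamini-Hochberg adjusted p-values instead.
#' @param covariates optional confound data.frame; when supplied, each
#'   score is itself residualized against the confounds (on its
#'   complete cases) before the rank correlation, so that voxels and
#'   scores are screened on the same adjusted scale. The default
#'   residualizes voxels only.
#' @return an object of class `feature_mask`: logical `masks` matrix
#'   (voxels x scores), logical `union` vector, per-score and union
#'   `counts`, `alpha`, and per-score complete-case `n`.
#' @export
select_features <- function(residualized, scores, alpha = 0.01,
                            adjust = c("none", "BH"), covariates = NULL) {
  adjust <- match.arg(adjust)
  alpha <- .check_prob(alpha, "alpha")
  X <- as.matrix(residualized)
  scores <- as.data.frame(scores)
  if (nrow(X) != nrow(scores)) {
    stop("`residualized` and `scores` must cover the same subjects",
         call. = FALSE)
  }
  masks <- matrix(FALSE, ncol(X), ncol(scores),
                  dimnames = list(NULL, names(scores)))
  nn <- integer(ncol(scores))
  for (k in seq_along(scores)) {
    y <- scores[[k]]
    ok <- is.finite(y)
    nn[k] <- sum(ok)
    if (nn[k] < 10L) {
      stop(sprintf("score `%s` has only %d complete cases (need >= 10)",
                   names(scores)[k], nn[k]), call. = FALSE)
    }
    yk <- y[ok]
    if (!is.null(covariates)) {
      yk <- as.vector(residualize(matrix(yk),
                                  as.data.frame(covariates)[ok, , drop = FALSE]))
    }
    p <- .spearman_screen(X[ok, , drop = FALSE], yk)
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    masks[, k] <- p < alpha
  }
  union <- apply(masks, 1, any)
  structure(list(
    masks = masks,
    union = union,
    counts = c(stats::setNames(as.integer(colSums(masks)), colnames(masks)),
               union = sum(union)),
    alpha = alpha,
    adjust = adjust,
    n_complete = stats::setNames(nn, names(scores))
  ), class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("Feature mask (Spearman screen, alpha = %g, %s):\n", x$alpha,
              if (x$adjust == "none") "uncorrected" else x$adjust))
  print(x$counts)
  invisible(x)
}
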