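# Biotype discovery: PCA to a variance target, Ward linkage on
# correlation distance, Calinski-Harabasz model selection, and a
# k-means stability check scored with Cohen's kappa.

#' PCA reduction to a cumulative explained-variance target
#'
#' Column-centres the input (unstandardized by default, matching
#' covariance PCA on residualized voxel values) and keeps the smallest
#' number of leading components whose cumulative explained-variance
#' ratio reaches `var_target`.
#'
#' @param X subjects x features numeric matrix.
#' @param var_target cumulative explained-variance target in (0, 1].
#' @param scale. standardize columns to unit variance before PCA.
#' @return object of class `component_scores`: `scores` (subjects x
#'   n_components), `explained_ratio` (all components), `n_components`,
#'   `var_target`, plus the `rotation` and `center` needed to project
#'   new subjects.
#' @export
pca_reduce <- function(X, var_target = 0.90, scale. = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (!is.numeric(var_target) || length(var_target) != 1L ||
      var_target <= 0 || var_target > 1) {
    stop("`var_target` must lie in (0, 1]", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- which(cumsum(ratio) >= var_target - 1e-12)[1]
  structure(list(
    scores = pc$x[, seq_len(ncomp), drop = FALSE],
    explained_ratio = ratio,
    n_components = ncomp,
    var_target = var_target,
    rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
    center = pc$center,
    scale = pc$scale
  ), class = "component_scores")
}

#' @export
print.component_scores <- function(x, ...) {
  cat(sprintf("%d components retained (%.1f%% of variance, target %.0f%%), %d subjects\n",
              x$n_components, 100 * sum(x$explained_ratio[seq_len(x$n_components)]),
              100 * x$var_target, nrow(x$scores)))
  invisible(x)
}

#' Pairwise correlation distance between subjects
#'
#' `d(i, j) = 1 - Pearson(row_i, row_j)`; symmetric with an exactly
#' zero diagonal, values in \[0, 2\].
#'
#' @param S subjects x components numeric matrix (>= 2 columns, no
#'   constant rows).
#' @return a dense symmetric distance matrix.
#' @export
correlation_distance <- function(S) {
  S <- as.matrix(S)
  if (ncol(S) < 2L) stop("need at least 2 components per subject", call. = FALSE)
  rsd <- apply(S, 1, stats::sd)
  if (any(rsd == 0)) {
    stop("constant component row for subject(s): ",
         paste(which(rsd == 0), collapse = ", "), call. = FALSE)
  }
  D <- 1 - stats::cor(t(S))
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

.check_distance <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8) ||
      any(diag(D) != 0) || any(D < -1e-12)) {
    stop("`D` must be a symmetric non-negative matrix with zero diagonal",
         call. = FALSE)
  }
  D
}

#' Ward hierarchical clustering on a dissimilarity matrix
#'
#' Agglomerates by the Lance-Williams Ward update applied directly to
#' the supplied dissimilarities (the classical `ward.D` scheme), then
#' cuts the tree at `k` clusters. On correlation distances this is
#' formally a heuristic -- Ward's variance argument assumes squared
#' Euclidean input -- and is used here exactly because it is the
#' field's standard recipe for patient subtyping; see
#' [ward_cluster_euclidean()] for the sensitivity variant.
#'
#' @param D symmetric dissimilarity matrix, zero diagonal.
#' @param k number of clusters, 2 <= k <= n (k = n gives singletons).
#' @return list of class `biotype_assignment`: integer `labels`,
#'   `merge`, `height`, the `hclust` object, and `k`.
#' @export
ward_cluster <- function(D, k) {
  D <- .check_distance(D)
  n <- nrow(D)
  k <- .check_count(k, "k")
  if (k > n) stop("`k` cannot exceed the number of subjects", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D")
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = unname(labels), merge = hc$merge,
                 height = hc$height, hclust = hc, k = k),
            class = "biotype_assignment")
}

#' @rdname ward_cluster
#' @param S subjects x components score matrix; rows are standardized
#'   before Euclidean Ward (`ward.D2`).
#' @export
ward_cluster_euclidean <- function(S, k) {
  S <- as.matrix(S)
  Z <- t(scale(t(S)))
  hc <- stats::hclust(stats::dist(Z), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = unname(labels), merge = hc$merge,
                 height = hc$height, hclust = hc, k = k),
            class = "biotype_assignment")
}

#' Calinski-Harabasz index
#'
#' `CH = [B / (k - 1)] / [W / (n - k)]` with between-cluster dispersion
#' `B = sum_c n_c ||mu_c - mu||^2` and within-cluster dispersion
#' `W = sum_c sum_i ||x_i - mu_c||^2`, computed with Euclidean geometry
#' in component space.
#'
#' @param S subjects x components matrix.
#' @param labels cluster labels (>= 2 non-empty clusters).
#' @return the CH value (larger = better separated).
#' @export
calinski_harabasz <- function(S, labels) {
  S <- as.matrix(S)
  labels <- as.integer(factor(labels))
  n <- nrow(S)
  k <- length(unique(labels))
  if (k < 2L || k >= n + 1L) stop("need 2 <= k <= n non-empty clusters",
                                  call. = FALSE)
  mu <- colMeans(S)
  B <- 0; W <- 0
  for (c in unique(labels)) {
    Sc <- S[labels == c, , drop = FALSE]
    muc <- colMeans(Sc)
    B <- B + nrow(Sc) * sum((muc - mu)^2)
    W <- W + sum(sweep(Sc, 2, muc)^2)
  }
  if (W == 0) stop("degenerate clustering: zero within-cluster dispersion",
                   call. = FALSE)
  (B / (k - 1)) / (W / (n - k))
}

#' Choose the cluster number by Calinski-Harabasz over Ward cuts
#'
#' Computes the Ward tree once on the correlation distances of `S` and
#' scores each candidate `k`-cut with [calinski_harabasz()] in
#' component space; returns the argmax.
#'
#' @param S subjects x components score matrix.
#' @param k_range candidate cluster numbers (default 2..10).
#' @return list: chosen `k`, named vector `ch_values`, the
#'   `biotype_assignment` at the chosen k.
#' @export
select_k <- function(S, k_range = 2:10) {
  S <- as.matrix(S)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > nrow(S) - 1L)) {
    stop("`k_range` must lie within 2 .. n - 1", call. = FALSE)
  }
  D <- correlation_distance(S)
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D")
  ch <- vapply(k_range, function(k) {
    calinski_harabasz(S, stats::cutree(hc, k = k))
  }, numeric(1))
  names(ch) <- k_range
  k_best <- k_range[which.max(ch)]
  assignment <- structure(
    list(labels = unname(stats::cutree(hc, k = k_best)), merge = hc$merge,
         height = hc$height, hclust = hc, k = k_best, ch_values = ch),
    class = "biotype_assignment")
  list(k = k_best, ch_values = ch, assignment = assignment)
}

#' Seeded best-of-n k-means (Lloyd)
#'
#' Runs Lloyd's algorithm from `n_init` seeded random initializations
#' and returns the labels of the run with the lowest within-cluster sum
#' of squares. An initialization that collapses to an empty cluster is
#' re-seeded.
#'
#' @param S subjects x components matrix.
#' @param k number of clusters (k = 1 allowed).
#' @param seed integer seed for the initializations.
#' @param n_init number of random restarts.
#' @return list of class `kmeans_result`: `labels`, `tot_withinss`,
#'   `objectives` (per successful init), `seed`, `n_init`.
#' @export
kmeans_cluster <- function(S, k, seed = 1L, n_init = 50L) {
  S <- as.matrix(S)
  k <- .check_count(k, "k")
  if (k > nrow(S)) stop("`k` cannot exceed the number of subjects", call. = FALSE)
  .with_seed(seed, {
    if (k == 1L) {
      centered <- sweep(S, 2, colMeans(S))
      return(structure(list(labels = rep(1L, nrow(S)),
                            tot_withinss = sum(centered^2),
                            objectives = sum(centered^2),
                            seed = seed, n_init = n_init),
                       class = "kmeans_result"))
    }
    best <- NULL
    objectives <- numeric(0)
    tries <- 0L
    while (length(objectives) < n_init && tries < 4L * n_init) {
      tries <- tries + 1L
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(S, centers = k, iter.max = 200L,
                                       nstart = 1L, algorithm = "Lloyd")),
        error = function(e) NULL)  # empty-cluster collapse: re-seed
      if (is.null(fit) || length(unique(fit$cluster)) < k) next
      objectives <- c(objectives, fit$tot.withinss)
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stop("k-means failed to produce k non-empty clusters",
                            call. = FALSE)
    structure(list(labels = unname(best$cluster),
                   tot_withinss = best$tot.withinss,
                   objectives = objectives, seed = seed, n_init = n_init),
              class = "kmeans_result")
  })
}

#' Cohen's kappa between two clusterings after label alignment
#'
#' Labels of `b` are re-mapped by the permutation that maximizes raw
#' agreement with `a` (exhaustive over permutations; intended for small
#' k), then Cohen's kappa `(p_o - p_e) / (1 - p_e)` is computed with
#' chance agreement `p_e` from the marginal products.
#'
#' @param labels_a,labels_b equal-length label vectors over the same
#'   subjects in the same order.
#' @return kappa in \[-1, 1\].
#' @export
kappa_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  a <- as.integer(factor(labels_a))
  b <- as.integer(factor(labels_b))
  ka <- max(a); kb <- max(b)
  if (kb > 7L) stop("exhaustive label alignment supports at most 7 clusters",
                    call. = FALSE)
  perms <- .permutations(kb)
  best_agree <- -1L
  best_b <- b
  for (i in seq_len(nrow(perms))) {
    bb <- perms[i, ][b]
    agree <- sum(bb == a)
    if (agree > best_agree) {
      best_agree <- agree
      best_b <- bb
    }
  }
  lev <- seq_len(max(ka, kb))
  tab <- table(factor(a, levels = lev), factor(best_b, levels = lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], k, after = pos - 1L)
    }
  }
  out
}

#' @export
print.biotype_assignment <- function(x, ...) {
  cat(sprintf("Biotype assignment: k = %d, sizes %s\n", x$k,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}
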