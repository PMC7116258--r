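# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (loops, base det(), explicit normal equations) so
# they share no code path with the implementation they check.

# per-voxel 3x3 Jacobian determinant via base det(); central/one-sided
# differences recomputed with explicit indexing
oracle_det_map <- function(field) {
  u <- field$u
  sp <- field$spacing_mm
  d <- dim(u)[1:3]
  g1 <- function(a, i, axis) {
    n <- d[axis]
    step <- function(j) {
      idx <- i
      idx[axis] <- j
      a[idx[1], idx[2], idx[3]]
    }
    if (i[axis] == 1) (step(2) - step(1)) / sp[axis]
    else if (i[axis] == n) (step(n) - step(n - 1)) / sp[axis]
    else (step(i[axis] + 1) - step(i[axis] - 1)) / (2 * sp[axis])
  }
  out <- array(NA_real_, dim = d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    J <- diag(3)
    for (a in 1:3) for (b in 1:3) {
      J[a, b] <- J[a, b] + g1(u[, , , a], c(x, y, z), b)
    }
    out[x, y, z] <- det(J)
  }
  out
}

# dense 3-D convolution with the same truncated 4-sigma kernel and
# boundary renormalization, accumulated offset-by-offset
oracle_smooth <- function(values, spacing, fwhm) {
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  d <- dim(values)
  kern <- lapply(1:3, function(ax) {
    s <- sigma_mm / spacing[ax]
    r <- max(0L, as.integer(ceiling(4 * s)))
    w <- exp(-((-r):r)^2 / (2 * s^2))
    list(r = r, w = w / sum(w))
  })
  acc <- array(0, dim = d)
  wsum <- array(0, dim = d)
  for (ox in -kern[[1]]$r:kern[[1]]$r)
    for (oy in -kern[[2]]$r:kern[[2]]$r)
      for (oz in -kern[[3]]$r:kern[[3]]$r) {
        w <- kern[[1]]$w[ox + kern[[1]]$r + 1] *
             kern[[2]]$w[oy + kern[[2]]$r + 1] *
             kern[[3]]$w[oz + kern[[3]]$r + 1]
        xs <- pmax(1, 1 - ox):pmin(d[1], d[1] - ox)
        ys <- pmax(1, 1 - oy):pmin(d[2], d[2] - oy)
        zs <- pmax(1, 1 - oz):pmin(d[3], d[3] - oz)
        acc[xs, ys, zs] <- acc[xs, ys, zs] +
          w * values[xs + ox, ys + oy, zs + oz]
        wsum[xs, ys, zs] <- wsum[xs, ys, zs] + w
      }
  acc / wsum
}

# explicit normal-equation residuals
oracle_residuals <- function(values, X) {
  beta <- solve(t(X) %*% X) %*% t(X) %*% values
  values - X %*% beta
}

# rank-with-ties then Pearson, plus the t-approximation p-value
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * pt(-abs(tval), n - 2))
}

# BH by scanning every candidate threshold
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k_star <- 0L
  for (i in seq_len(m)) if (p[o[i]] <= i / m * q) k_star <- i
  out <- rep(FALSE, m)
  if (k_star > 0) out[o[seq_len(k_star)]] <- TRUE
  out
}

# from-scratch Ward: merge the pair of clusters minimizing the increase
# in total within-cluster sum of squares over the raw points
oracle_ward_merges <- function(P) {
  n <- nrow(P)
  clusters <- as.list(seq_len(n))
  ess <- function(idx) {
    if (length(idx) == 1) return(0)
    Pc <- P[idx, , drop = FALSE]
    sum(sweep(Pc, 2, colMeans(Pc))^2)
  }
  merges <- list()
  ids <- -(seq_len(n))
  repeat {
    m <- length(clusters)
    if (m == 1) break
    best <- NULL; bestcost <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      cost <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (cost < bestcost - 1e-12) { bestcost <- cost; best <- c(i, j) }
    }
    merges[[length(merges) + 1]] <- sort(c(ids[best[1]], ids[best[2]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    ids[best[1]] <- length(merges)
    clusters[[best[2]]] <- NULL
    ids <- ids[-best[2]]
  }
  do.call(rbind, merges)
}

# small cohort config shared by several tests
tiny_config <- function(seed = 1L, ...) {
  simulation_config(n_pd = 60, n_hc = 30, grid_shape = c(12, 12, 12),
                    seed = seed, ...)
}

score_cols <- c("updrs1", "updrs2", "updrs3", "updrs_total", "tremor", "pigd")
confound_cols <- c("age", "sex", "education", "race", "site")
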