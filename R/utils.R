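#' @keywords internal
"_PACKAGE"

# Internal argument checks shared across modules. All stop() with
# caller-facing messages; no condition classes beyond base ones.

.check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= 1", name), call. = FALSE)
  }
  as.integer(x)
}

.check_positive <- function(x, name, len = 1L) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
  x
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must lie strictly in (0, 1)", name), call. = FALSE)
  }
  x
}

# Deterministic per-stage seed spawned from one master seed. Offsets are
# small fixed primes so all spawned seeds stay well below 2^31.
.stage_seed <- function(master, stage) {
  offsets <- c(
    simulate = 101L, displacement = 211L, longitudinal = 307L,
    dbm = 401L, select = 503L, biotype = 601L, kmeans = 701L,
    validate = 809L, progress = 907L
  )
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer(master %% 2147000000L) + offsets[[stage]]
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same
#' subjects, used throughout to score recovery of planted biotypes.
#' Equals 1 for identical partitions (up to relabeling) and has
#' expectation 0 for independent random partitions.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(0)
  (sij - expected) / (maxidx - expected)
}

# Rank-statistic AUC (Mann-Whitney). `score` is oriented so that larger
# values favour the positive class.
.rank_auc <- function(score, is_pos) {
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
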