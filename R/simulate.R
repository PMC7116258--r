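# Seeded synthetic cohort generator with known ground truth.
#
# The generator emulates the structure of a multi-site de novo PD
# cohort: per-subject DBM maps on a small regular grid with a planted
# "subcortical" block whose mean is shifted down in biotype 1 and up in
# biotype 2 (controls unshifted), additive site/age/sex confound
# effects, six baseline clinical scores driven by the subject's mean
# planted-block signal, and a longitudinal visit schedule (quarterly in
# year one, six-monthly thereafter) with biotype-specific outcome
# slopes and correlated random intercepts/slopes.

SCORE_NAMES <- c("updrs1", "updrs2", "updrs3", "updrs_total", "tremor", "pigd")

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the discovery cohort the pipeline is designed for:
#' 314 patients split 36.31%/63.69% across two biotypes, 143 controls,
#' ages 61 +/- 9.5 years with 34.1% women, a 24^3 voxel grid, and 13
#' visits over five years (baseline, quarterly in year 1, six-monthly
#' thereafter).
#'
#' @param n_pd,n_hc numbers of PD patients and healthy controls.
#' @param biotype_fractions proportions of PD subjects per biotype;
#'   must sum to 1 (within 1e-12).
#' @param grid_shape 3 positive integers, the voxel grid.
#' @param voxel_spacing_mm voxel spacing in mm (length 3 or scalar).
#' @param n_sites number of acquisition sites.
#' @param effect_size standardized mean shift of the planted subcortical
#'   signal (voxel noise has unit SD, so this is in SD units); biotype 1
#'   is shifted by `-effect_size`, biotype 2 by `+effect_size`.
#' @param score_noise_sd SD of the additive noise on clinical scores.
#' @param score_link per-score coefficient linking the subject's mean
#'   planted-block DBM signal to each clinical score (named vector over
#'   `updrs1, updrs2, updrs3, updrs_total, tremor, pigd`).
#' @param score_age_coef additive age effect on every clinical score,
#'   points per year of age. Set to 0 (together with `score_link = 0`
#'   and `effect_size = 0`) for a score-noise-only null cohort.
#' @param visit_months strictly increasing visit schedule starting at 0.
#' @param slope_by_biotype 6 x 2 matrix of per-month outcome slopes
#'   (rows = scores, columns = biotypes). The default gives biotype 1
#'   faster progression on every score except tremor, where the two
#'   biotypes share a slope.
#' @param rand_intercept_sd,rand_slope_sd,rand_cor,resid_sd variance
#'   components of the longitudinal model (subject intercept SD, subject
#'   slope SD, their correlation, residual SD).
#' @param dropout_rate per-record probability that a post-baseline visit
#'   row is missing (baseline rows are always retained).
#' @param site_sd,age_coef,sex_coef confound effects on voxels: per-site
#'   offsets drawn from N(0, site_sd^2); additive `age_coef * (age - 61)`
#'   and `sex_coef * I(male)`.
#' @param seed integer seed; fixes every random draw in the generator.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_pd = 314, n_hc = 143,
                              biotype_fractions = c(114, 200) / 314,
                              grid_shape = c(24, 24, 24),
                              voxel_spacing_mm = c(2, 2, 2),
                              n_sites = 5,
                              effect_size = 0.8,
                              score_noise_sd = 2,
                              score_link = c(updrs1 = 2, updrs2 = 2,
                                             updrs3 = 4, updrs_total = 6,
                                             tremor = 1, pigd = 1.5),
                              score_age_coef = 0.05,
                              visit_months = c(0, 3, 6, 9, 12, 18, 24,
                                               30, 36, 42, 48, 54, 60),
                              slope_by_biotype = cbind(
                                biotype1 = c(0.06, 0.08, 0.25, 0.39, 0.01, 0.030),
                                biotype2 = c(0.03, 0.04, 0.15, 0.22, 0.01, 0.015)),
                              rand_intercept_sd = 2, rand_slope_sd = 0.1,
                              rand_cor = 0, resid_sd = 1,
                              dropout_rate = 0,
                              site_sd = 0.1, age_coef = -0.01, sex_coef = 0.05,
                              seed = 1L) {
  n_pd <- .check_count(n_pd, "n_pd")
  n_hc <- .check_count(n_hc, "n_hc")
  n_sites <- .check_count(n_sites, "n_sites")
  if (!is.numeric(biotype_fractions) || length(biotype_fractions) < 2L ||
      any(biotype_fractions < 0) || abs(sum(biotype_fractions) - 1) > 1e-12) {
    stop("`biotype_fractions` must be non-negative and sum to 1 (within 1e-12)",
         call. = FALSE)
  }
  grid_shape <- vapply(grid_shape, .check_count, integer(1), name = "grid_shape")
  if (length(grid_shape) != 3L) stop("`grid_shape` needs 3 entries", call. = FALSE)
  if (length(voxel_spacing_mm) == 1L) voxel_spacing_mm <- rep(voxel_spacing_mm, 3)
  .check_positive(voxel_spacing_mm, "voxel_spacing_mm", 3L)
  if (!is.numeric(effect_size) || length(effect_size) != 1L || effect_size < 0) {
    stop("`effect_size` must be a single non-negative number", call. = FALSE)
  }
  .check_positive(score_noise_sd, "score_noise_sd")
  if (length(visit_months) < 1L || visit_months[1] != 0 ||
      any(diff(visit_months) <= 0) || any(visit_months < 0)) {
    stop("`visit_months` must be strictly increasing and start at 0",
         call. = FALSE)
  }
  slope_by_biotype <- as.matrix(slope_by_biotype)
  if (nrow(slope_by_biotype) != length(SCORE_NAMES) ||
      ncol(slope_by_biotype) != length(biotype_fractions)) {
    stop("`slope_by_biotype` must be 6 scores x n biotypes", call. = FALSE)
  }
  rownames(slope_by_biotype) <- SCORE_NAMES
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must be in [0, 1)", call. = FALSE)
  }
  score_link <- score_link[SCORE_NAMES]
  if (any(is.na(score_link))) stop("`score_link` must name all six scores",
                                   call. = FALSE)
  structure(list(
    n_pd = n_pd, n_hc = n_hc, biotype_fractions = biotype_fractions,
    grid_shape = grid_shape, voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    n_sites = n_sites, effect_size = effect_size,
    score_noise_sd = score_noise_sd, score_link = score_link,
    score_age_coef = score_age_coef,
    visit_months = as.numeric(visit_months), slope_by_biotype = slope_by_biotype,
    rand_intercept_sd = rand_intercept_sd, rand_slope_sd = rand_slope_sd,
    rand_cor = rand_cor, resid_sd = resid_sd, dropout_rate = dropout_rate,
    site_sd = site_sd, age_coef = age_coef, sex_coef = sex_coef,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Largest-remainder apportionment of n subjects across fractions:
# counts are exact for fractions that are multiples of 1/n and always
# sum to n.
.largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

# Central "subcortical" block mask, strictly inside the grid.
.planted_mask <- function(grid_shape) {
  mask <- array(FALSE, dim = grid_shape)
  idx <- lapply(grid_shape, function(n) {
    side <- max(3L, round(n / 4))
    lo <- max(2L, floor((n - side) / 2) + 1L)
    lo:(lo + side - 1L)
  })
  mask[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  mask
}

#' Simulate a synthetic DBM cohort with planted biotypes
#'
#' Generates per-subject voxel maps (baseline value 1, unit-variance
#' gaussian voxel noise, additive site/age/sex effects, and the planted
#' biotype shift inside a central subcortical block), a cohort table of
#' covariates and six baseline clinical scores linearly linked to the
#' subject's mean planted-block signal, and the ground truth needed to
#' score downstream recovery. Bit-reproducible for a fixed seed.
#'
#' @param config a [simulation_config].
#' @return a list of class `synthetic_cohort` with elements
#'   `maps` (subjects x voxels matrix, rows named by subject),
#'   `cohort` (data.frame: subject_id, group, age, sex, education, race,
#'   site, and the six score columns), `truth` (planted labels, mask,
#'   slopes, confound coefficients, variance components), and grid
#'   metadata (`grid_shape`, `spacing_mm`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(.stage_seed(config$seed, "simulate"), {
    n <- config$n_pd + config$n_hc
    ids <- sprintf("S%04d", seq_len(n))
    group <- c(rep("PD", config$n_pd), rep("HC", config$n_hc))

    # biotype allocation: exact largest-remainder counts, then a seeded
    # permutation assigns labels to subjects
    counts <- .largest_remainder(config$n_pd, config$biotype_fractions)
    labels <- sample(rep.int(seq_along(counts), counts))

    # covariates
    age <- round(rnorm(n, 61.0, 9.5), 1)
    sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.659, 0.341))
    education <- pmax(6, round(rnorm(n, 15, 3)))
    race <- sample(c("white", "other"), n, replace = TRUE, prob = c(0.92, 0.08))
    site <- paste0("site", (sample(n) %% config$n_sites) + 1L)

    site_eff <- rnorm(config$n_sites, 0, config$site_sd)
    names(site_eff) <- paste0("site", seq_len(config$n_sites))

    mask <- .planted_mask(config$grid_shape)
    n_vox <- prod(config$grid_shape)

    shift <- numeric(n)
    shift[group == "PD"] <- c(-1, 1, rep(0, max(0, length(counts) - 2)))[labels] *
      config$effect_size

    maps <- matrix(rnorm(n * n_vox), nrow = n)
    maps <- maps + 1 +
      site_eff[site] +
      config$age_coef * (age - 61) +
      config$sex_coef * (sex == "male")
    maps[, as.vector(mask)] <- maps[, as.vector(mask)] + shift

    rownames(maps) <- ids

    # clinical scores: linear in the subject's mean planted-block DBM
    # signal (centred at the baseline value 1), a small age term, noise
    mean_mask <- rowMeans(maps[, as.vector(mask), drop = FALSE]) - 1
    intercepts <- c(updrs1 = 5.6, updrs2 = 5.9, updrs3 = 20.7,
                    updrs_total = 32.2, tremor = 0.4, pigd = 0.2)
    scores <- sapply(SCORE_NAMES, function(k) {
      intercepts[[k]] - config$score_link[[k]] * mean_mask +
        config$score_age_coef * (age - 61) + rnorm(n, 0, config$score_noise_sd)
    })
    colnames(scores) <- SCORE_NAMES

    cohort <- data.frame(
      subject_id = ids, group = group, age = age, sex = sex,
      education = education, race = race, site = site,
      stringsAsFactors = FALSE
    )
    cohort <- cbind(cohort, as.data.frame(scores))

    truth <- list(
      biotype = stats::setNames(labels, ids[group == "PD"]),
      biotype_counts = counts,
      mask = mask,
      slope_by_biotype = config$slope_by_biotype,
      site_effects = site_eff,
      age_coef = config$age_coef, sex_coef = config$sex_coef,
      effect_size = config$effect_size,
      variance_components = c(intercept_sd = config$rand_intercept_sd,
                              slope_sd = config$rand_slope_sd,
                              cor = config$rand_cor,
                              resid_sd = config$resid_sd)
    )

    structure(list(maps = maps, cohort = cohort, truth = truth,
                   grid_shape = config$grid_shape,
                   spacing_mm = config$voxel_spacing_mm,
                   config = config),
              class = "synthetic_cohort")
  })
}

#' Extract one subject's map as a DBM image
#'
#' @param cohort a `synthetic_cohort`.
#' @param subject subject id or row index.
#' @return a [dbm_image].
#' @export
cohort_map <- function(cohort, subject) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  v <- cohort$maps[subject, ]
  dbm_image(array(v, dim = cohort$grid_shape), spacing_mm = cohort$spacing_mm)
}

#' Simulate a displacement field fixture
#'
#' Three modes: `zero` (identity transform), `affine` (uniform scaling
#' `u(x) = (s - 1) x`, whose exact Jacobian determinant is `s^3`
#' everywhere), and `smooth_random` (a seeded band-limited random field,
#' rejected if it is not diffeomorphic, i.e. if the determinant map is
#' not strictly positive).
#'
#' @param grid_shape 3 positive integers.
#' @param mode `"zero"`, `"affine"`, or `"smooth_random"`.
#' @param s affine scale factor, > 0.
#' @param amplitude smooth_random displacement amplitude in voxel units.
#' @param seed seed for smooth_random.
#' @param spacing_mm voxel spacing.
#' @return a [displacement_field].
#' @export
simulate_displacement_field <- function(grid_shape,
                                        mode = c("zero", "affine", "smooth_random"),
                                        s = 1.1, amplitude = 0.2, seed = 1L,
                                        spacing_mm = c(1, 1, 1)) {
  mode <- match.arg(mode)
  grid_shape <- vapply(grid_shape, .check_count, integer(1), name = "grid_shape")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3)
  u <- array(0, dim = c(grid_shape, 3))
  if (mode == "affine") {
    if (!is.numeric(s) || length(s) != 1L || s <= 0) {
      stop("affine scale `s` must be > 0", call. = FALSE)
    }
    for (axis in 1:3) {
      coord <- (seq_len(grid_shape[axis]) - 1) * spacing_mm[axis]
      u[, , , axis] <- aperm(
        array(coord, dim = grid_shape[c(axis, setdiff(1:3, axis))]),
        order(c(axis, setdiff(1:3, axis)))
      ) * (s - 1)
    }
  } else if (mode == "smooth_random") {
    u <- .with_seed(seed, {
      raw <- array(rnorm(prod(grid_shape) * 3), dim = c(grid_shape, 3))
      for (k in 1:3) {
        sm <- smooth_fwhm(dbm_image(raw[, , , k]), fwhm_mm = 5)$values
        sm <- sm / max(abs(sm)) * amplitude * spacing_mm[k]
        raw[, , , k] <- sm
      }
      raw
    })
    field <- displacement_field(u, spacing_mm)
    det <- jacobian_determinant_map(field)$values
    if (min(det) <= 0) {
      bad <- which(det == min(det), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "amplitude %g yields a non-diffeomorphic field: det J = %.3g at voxel (%d, %d, %d)",
        amplitude, min(det), bad[1], bad[2], bad[3]), call. = FALSE)
    }
    return(field)
  }
  displacement_field(u, spacing_mm)
}

#' Simulate longitudinal outcomes with biotype-specific slopes
#'
#' For each PD subject and each of the six outcomes:
#' `y(t) = intercept + b0_i + (slope[biotype] + b1_i) t + e`, with
#' `(b0_i, b1_i)` jointly gaussian (SDs and correlation from the
#' config) and gaussian residuals. All visit months are emitted for
#' every subject; if `dropout_rate > 0`, post-baseline rows are dropped
#' independently with that probability.
#'
#' @param config the [simulation_config] used to build the cohort.
#' @param ground_truth the `truth` element of [simulate_cohort()] output.
#' @param cohort optional cohort data.frame; when supplied, covariate
#'   columns (age, sex, race, site) are joined onto the long table.
#' @return a long-format data.frame of class `longitudinal_table`:
#'   subject_id, visit_month, outcome, value, biotype (+ covariates).
#' @export
simulate_longitudinal <- function(config, ground_truth, cohort = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(ground_truth$biotype)) stop("`ground_truth` lacks biotype labels",
                                          call. = FALSE)
  .with_seed(.stage_seed(config$seed, "longitudinal"), {
    ids <- names(ground_truth$biotype)
    biotype <- ground_truth$biotype
    tt <- config$visit_months
    n <- length(ids)

    intercepts <- c(updrs1 = 5.6, updrs2 = 5.9, updrs3 = 20.7,
                    updrs_total = 32.2, tremor = 0.4, pigd = 0.2)

    rho <- config$rand_cor
    rows <- vector("list", length(SCORE_NAMES))
    for (k in seq_along(SCORE_NAMES)) {
      outc <- SCORE_NAMES[k]
      z <- matrix(rnorm(2 * n), ncol = 2)
      b0 <- config$rand_intercept_sd * z[, 1]
      b1 <- config$rand_slope_sd * (rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
      slope <- config$slope_by_biotype[outc, biotype] + b1
      y <- outer(b0 + intercepts[[outc]], rep(1, length(tt))) +
        outer(slope, tt) +
        matrix(rnorm(n * length(tt), 0, config$resid_sd), nrow = n)
      rows[[k]] <- data.frame(
        subject_id = rep(ids, times = length(tt)),
        visit_month = rep(tt, each = n),
        outcome = outc,
        value = as.vector(y),
        biotype = rep(unname(biotype), times = length(tt)),
        stringsAsFactors = FALSE
      )
    }
    long <- do.call(rbind, rows)
    if (config$dropout_rate > 0) {
      keep <- long$visit_month == 0 |
        runif(nrow(long)) >= config$dropout_rate
      long <- long[keep, , drop = FALSE]
    }
    if (!is.null(cohort)) {
      jcols <- intersect(c("age", "sex", "race", "site"), names(cohort))
      long <- merge(long, cohort[, c("subject_id", jcols)], by = "subject_id",
                    sort = FALSE)
    }
    long <- long[order(long$outcome, long$subject_id, long$visit_month), ]
    rownames(long) <- NULL
    class(long) <- c("longitudinal_table", "data.frame")
    long
  })
}
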