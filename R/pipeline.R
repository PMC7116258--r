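# End-to-end orchestration: simulate -> dbm -> select -> biotype ->
# validate -> progress, with a written manifest so a run is fully
# reproducible from one master seed.

#' Pipeline run configuration
#'
#' Bundles all stage parameters, stage toggles, and the master seed.
#' Every stage derives its own seed deterministically from the master
#' seed, so one integer reproduces a whole run. Parameters are
#' validated here, before any stage executes.
#'
#' @param seed master integer seed.
#' @param out_dir output directory (created if needed).
#' @param n_pd,n_hc,effect_size,grid_shape,... forwarded to
#'   [simulation_config()].
#' @param fwhm_mm smoothing FWHM in mm applied to all maps (`NULL`
#'   skips smoothing). Default 8 mm, the conventional DBM choice.
#' @param alpha per-score selection level.
#' @param var_target PCA cumulative explained-variance target.
#' @param k_range candidate cluster numbers.
#' @param folds classifier CV folds.
#' @param q_map,q_table,q_progress FDR levels for contrast maps, the
#'   baseline table, and the progression summary.
#' @param write_nifti write one NIfTI volume per subject map.
#' @param stages named logical vector toggling
#'   simulate/dbm/select/biotype/validate/progress.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("pdbiotype_run_"),
                            n_pd = 120, n_hc = 60, effect_size = 0.8,
                            grid_shape = c(24, 24, 24),
                            fwhm_mm = 8, alpha = 0.01, var_target = 0.90,
                            k_range = 2:10, folds = 10L,
                            q_map = 0.005, q_table = 0.05, q_progress = 0.05,
                            write_nifti = FALSE,
                            stages = c(simulate = TRUE, dbm = TRUE,
                                       select = TRUE, biotype = TRUE,
                                       validate = TRUE, progress = TRUE),
                            ...) {
  .check_prob(alpha, "alpha")
  .check_prob(q_map, "q_map")
  .check_prob(q_table, "q_table")
  .check_prob(q_progress, "q_progress")
  if (var_target <= 0 || var_target > 1) stop("`var_target` must be in (0, 1]",
                                              call. = FALSE)
  if (!is.null(fwhm_mm)) .check_positive(fwhm_mm, "fwhm_mm")
  sim <- simulation_config(n_pd = n_pd, n_hc = n_hc,
                           effect_size = effect_size,
                           grid_shape = grid_shape, seed = seed, ...)
  all_stages <- c("simulate", "dbm", "select", "biotype", "validate", "progress")
  st <- stats::setNames(rep(TRUE, length(all_stages)), all_stages)
  st[names(stages)] <- stages
  structure(list(
    seed = as.integer(seed), out_dir = out_dir, sim = sim,
    fwhm_mm = fwhm_mm, alpha = alpha, var_target = var_target,
    k_range = k_range, folds = as.integer(folds),
    q_map = q_map, q_table = q_table, q_progress = q_progress,
    write_nifti = isTRUE(write_nifti), stages = st
  ), class = "pipeline_config")
}

.require_stage <- function(result, what, needed_by, run_first) {
  if (is.null(result[[what]])) {
    stop(sprintf("stage `%s` needs `%s`; enable/run stage `%s` first",
                 needed_by, what, run_first), call. = FALSE)
  }
  result[[what]]
}

#' Run the full biotyping pipeline on a synthetic cohort
#'
#' Executes the enabled stages in dependency order:
#' \describe{
#'   \item{simulate}{synthetic cohort + longitudinal outcomes}
#'   \item{dbm}{FWHM smoothing of all subject maps}
#'   \item{select}{confound residualization (fitted within PD) and the
#'     Spearman voxel screen against the six baseline scores}
#'   \item{biotype}{PCA to the variance target, Ward on correlation
#'     distance with Calinski-Harabasz k selection, k-means kappa check;
#'     discovered clusters are numbered so that biotype 1 has the lower
#'     mean planted-signal (union-mask) DBM value}
#'   \item{validate}{biotype-vs-control contrast maps (FDR `q_map`),
#'     baseline comparison table, cross-validated SVM on the union-mask
#'     residualized voxels}
#'   \item{progress}{per-outcome mixed models contrasting the
#'     *discovered* biotypes' slopes, BH-adjusted across outcomes}
#' }
#' Tables are written as CSV under `config$out_dir`, optionally one
#' NIfTI volume per subject, and a YAML manifest (parameter echo, per
#' file md5, wall time, seed) is written last.
#'
#' @param config a [pipeline_config].
#' @return list of class `pipeline_result` with all in-memory stage
#'   outputs plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)
  files <- character()
  put_csv <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  if (config$stages[["simulate"]]) {
    res$cohort <- simulate_cohort(config$sim)
    res$longitudinal <- simulate_longitudinal(config$sim, res$cohort$truth,
                                              cohort = res$cohort$cohort)
    put_csv(res$cohort$cohort, "cohort.csv")
    put_csv(res$longitudinal, "longitudinal.csv")
  }

  if (config$stages[["dbm"]]) {
    cohort <- .require_stage(res, "cohort", "dbm", "simulate")
    if (!is.null(config$fwhm_mm)) {
      sm <- cohort$maps
      for (i in seq_len(nrow(sm))) {
        img <- smooth_fwhm(dbm_image(array(sm[i, ], dim = cohort$grid_shape),
                                     spacing_mm = cohort$spacing_mm),
                           config$fwhm_mm)
        sm[i, ] <- as.vector(img$values)
      }
      res$maps <- sm
    } else {
      res$maps <- cohort$maps
    }
    if (config$write_nifti) {
      nii_dir <- file.path(config$out_dir, "dbm")
      dir.create(nii_dir, showWarnings = FALSE)
      for (i in seq_len(nrow(res$maps))) {
        path <- file.path(nii_dir, paste0(rownames(res$maps)[i], ".nii.gz"))
        write_dbm_nifti(dbm_image(array(res$maps[i, ], dim = cohort$grid_shape),
                                  spacing_mm = cohort$spacing_mm), path)
        files <- c(files, path)
      }
    }
  }

  if (config$stages[["select"]]) {
    cohort <- .require_stage(res, "cohort", "select", "simulate")
    maps <- .require_stage(res, "maps", "select", "dbm")
    pd <- cohort$cohort$group == "PD"
    covars <- cohort$cohort[pd, c("age", "sex", "education", "race", "site")]
    res$residualized_pd <- residualize(maps[pd, , drop = FALSE], covars)
    res$residualized_hc <- residualize_apply(
      res$residualized_pd, maps[!pd, , drop = FALSE],
      cohort$cohort[!pd, c("age", "sex", "education", "race", "site")])
    res$feature_mask <- select_features(
      res$residualized_pd, cohort$cohort[pd, SCORE_NAMES],
      alpha = config$alpha)
    put_csv(data.frame(score = names(res$feature_mask$counts),
                       n_voxels = as.integer(res$feature_mask$counts)),
            "selected_voxel_counts.csv")
  }

  if (config$stages[["biotype"]]) {
    fm <- .require_stage(res, "feature_mask", "biotype", "select")
    if (sum(fm$union) < 2L) stop("fewer than 2 selected voxels; cannot biotype",
                                 call. = FALSE)
    Xsel <- res$residualized_pd[, fm$union, drop = FALSE]
    res$pca <- pca_reduce(Xsel, var_target = config$var_target)
    res$selection <- select_k(res$pca$scores, k_range = config$k_range)
    assignment <- res$selection$assignment

    # number clusters by mean union-mask signal, ascending: biotype 1 is
    # the smaller-volume cluster, matching the naming convention of a
    # contraction-vs-expansion biotype pair
    msig <- tapply(rowMeans(Xsel), assignment$labels, mean)
    remap <- stats::setNames(rank(msig, ties.method = "first"), names(msig))
    assignment$labels <- as.integer(remap[as.character(assignment$labels)])
    res$biotype <- assignment

    km <- kmeans_cluster(res$pca$scores, k = assignment$k,
                         seed = .stage_seed(config$seed, "kmeans"))
    res$kmeans <- km
    res$kappa <- kappa_agreement(assignment$labels, km$labels)
    res$shares <- report_biotype_shares(assignment$labels)

    pd_ids <- rownames(res$maps)[res$cohort$cohort$group == "PD"]
    put_csv(data.frame(subject_id = pd_ids, biotype = assignment$labels),
            "biotype_labels.csv")
    put_csv(linkage_edges(assignment), "linkage.csv")
    put_csv(res$shares, "biotype_shares.csv")
  }

  if (config$stages[["validate"]]) {
    assignment <- .require_stage(res, "biotype", "validate", "biotype")
    cohort <- res$cohort$cohort
    pd <- cohort$group == "PD"
    covars_all <- cohort[, c("age", "sex", "education", "race", "site")]
    res$contrast_maps <- lapply(seq_len(assignment$k), function(b) {
      in_b <- which(pd)[assignment$labels == b]
      voxelwise_group_ttest(res$maps[in_b, , drop = FALSE],
                            res$maps[!pd, , drop = FALSE],
                            covariates = covars_all[c(in_b, which(!pd)), ],
                            q = config$q_map)
    })
    res$baseline_table <- baseline_comparison(
      cohort[pd, ], assignment$labels,
      continuous = c("age", "education", SCORE_NAMES),
      categorical = c("sex", "race"),
      q = config$q_table)
    feats <- res$residualized_pd[, res$feature_mask$union, drop = FALSE]
    res$classifier <- crossval_svm(feats, assignment$labels,
                                   folds = config$folds,
                                   seed = .stage_seed(config$seed, "validate"),
                                   positive = "1")
    put_csv(res$baseline_table, "baseline_comparison.csv")
    put_csv(data.frame(metric = c("accuracy", "sensitivity", "specificity", "auc",
                                  "kappa_vs_kmeans"),
                       value = c(res$classifier$accuracy,
                                 res$classifier$sensitivity,
                                 res$classifier$specificity,
                                 res$classifier$auc, res$kappa)),
            "classifier_metrics.csv")
  }

  if (config$stages[["progress"]]) {
    assignment <- .require_stage(res, "biotype", "progress", "biotype")
    long <- .require_stage(res, "longitudinal", "progress", "simulate")
    pd_ids <- rownames(res$maps)[res$cohort$cohort$group == "PD"]
    discovered <- stats::setNames(assignment$labels, pd_ids)
    long$biotype <- discovered[long$subject_id]
    res$progression <- progression_summary(long, q = config$q_progress)
    put_csv(as.data.frame(res$progression), "progression_summary.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pdbiotype")),
    seed = config$seed,
    parameters = list(
      n_pd = config$sim$n_pd, n_hc = config$sim$n_hc,
      effect_size = config$sim$effect_size,
      grid_shape = config$sim$grid_shape, fwhm_mm = config$fwhm_mm,
      alpha = config$alpha, var_target = config$var_target,
      k_range = range(config$k_range), folds = config$folds,
      q_map = config$q_map, q_table = config$q_table,
      q_progress = config$q_progress),
    stages = as.list(config$stages),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f)))
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  yaml::write_yaml(manifest$parameters, file.path(config$out_dir, "config.yaml"))
  res$manifest <- manifest
  class(res) <- "pipeline_result"
  res
}

#' Linkage tree as an edge list
#'
#' Flattens an agglomeration tree into a CSV-friendly edge list: one
#' row per merge with the two children (negative = leaf index, positive
#' = earlier merge) and the merge height.
#'
#' @param assignment a `biotype_assignment`.
#' @return data.frame: step, child1, child2, height.
#' @export
linkage_edges <- function(assignment) {
  data.frame(step = seq_len(nrow(assignment$merge)),
             child1 = assignment$merge[, 1],
             child2 = assignment$merge[, 2],
             height = assignment$height)
}

#' Cluster share table
#'
#' Per-cluster count and percentage of the total, percentages rounded
#' to 2 decimals (e.g. counts 114 and 200 of 314 give 36.31 and 63.69).
#'
#' @param labels cluster label vector, or a named/unnamed count vector
#'   via `counts`.
#' @param counts per-cluster counts, as an alternative to `labels`.
#' @return data.frame: cluster, n, share_pct.
#' @export
report_biotype_shares <- function(labels = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (is.null(labels) || length(labels) == 0L) stop("empty labels",
                                                      call. = FALSE)
    tab <- table(labels)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
  }
  if (length(counts) == 0L || sum(counts) == 0) stop("empty input", call. = FALSE)
  if (is.null(names(counts))) names(counts) <- seq_along(counts)
  data.frame(cluster = names(counts), n = as.integer(counts),
             share_pct = round(100 * counts / sum(counts), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Verify a run manifest against the files on disk
#'
#' Recomputes the md5 of every file recorded in `manifest.yaml`; a
#' tampered or missing intermediate shows up as `FALSE`.
#'
#' @param out_dir the pipeline output directory.
#' @return named logical vector, one entry per recorded file.
#' @export
verify_manifest <- function(out_dir) {
  manifest <- yaml::read_yaml(file.path(out_dir, "manifest.yaml"))
  vapply(names(manifest$files), function(f) {
    path <- if (file.exists(file.path(out_dir, f))) file.path(out_dir, f)
            else file.path(out_dir, "dbm", f)
    file.exists(path) &&
      identical(unname(tools::md5sum(path)), manifest$files[[f]])
  }, logical(1))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pdbiotype pipeline run\n")
  if (!is.null(x$cohort)) {
    cat(sprintf("  cohort: %d PD / %d HC on a %s grid\n",
                x$config$sim$n_pd, x$config$sim$n_hc,
                paste(x$config$sim$grid_shape, collapse = "x")))
  }
  if (!is.null(x$feature_mask)) {
    cat(sprintf("  selected voxels (union): %d\n",
                x$feature_mask$counts[["union"]]))
  }
  if (!is.null(x$biotype)) {
    sh <- x$shares
    cat(sprintf("  biotypes: k = %d (%s), kappa vs k-means %.2f\n",
                x$biotype$k,
                paste(sprintf("%s: %d [%.2f%%]", sh$cluster, sh$n, sh$share_pct),
                      collapse = ", "),
                x$kappa))
  }
  if (!is.null(x$classifier)) {
    cat(sprintf("  classifier: accuracy %.1f%%, AUC %.2f\n",
                100 * x$classifier$accuracy, x$classifier$auc))
  }
  if (!is.null(x$progression)) {
    sig <- x$progression$outcome[x$progression$significant]
    cat(sprintf("  progression: %d/%d outcomes differ after FDR (%s)\n",
                length(sig), nrow(x$progression), paste(sig, collapse = ", ")))
  }
  invisible(x)
}
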