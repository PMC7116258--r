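# Shared configuration for the analysis workflow. Every numbered script
# sources this file; the master seed makes each stage reproducible
# without passing binary intermediates between scripts (cohort
# regeneration is deterministic and takes seconds).

library(pdbiotype)

MASTER_SEED <- 20260921L
RESULTS_DIR <- file.path("results", "analysis")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# Desk-scale analogue of the discovery cohort: 24^3 grid, 120 patients
# and 60 controls, two planted biotypes at a 0.8 SD subcortical
# contrast, 8 mm FWHM smoothing, quarterly-then-biannual visits.
study_config <- function() {
  simulation_config(n_pd = 120, n_hc = 60, effect_size = 0.8,
                    grid_shape = c(24, 24, 24), seed = MASTER_SEED)
}

CONFOUNDS <- c("age", "sex", "education", "race", "site")
SCORES <- c("updrs1", "updrs2", "updrs3", "updrs_total", "tremor", "pigd")

# deterministic reconstruction of the stages scripts depend on
rebuild_cohort <- function() simulate_cohort(study_config())

rebuild_smoothed <- function(co = rebuild_cohort(), fwhm = 8) {
  maps <- co$maps
  for (i in seq_len(nrow(maps))) {
    maps[i, ] <- as.vector(smooth_fwhm(
      dbm_image(array(maps[i, ], dim = co$grid_shape),
                spacing_mm = co$spacing_mm), fwhm)$values)
  }
  maps
}

rebuild_selection <- function(co = rebuild_cohort(), maps = rebuild_smoothed(co)) {
  pd <- co$cohort$group == "PD"
  resid_pd <- residualize(maps[pd, ], co$cohort[pd, CONFOUNDS])
  list(
    pd = pd,
    resid_pd = resid_pd,
    resid_hc = residualize_apply(resid_pd, maps[!pd, ],
                                 co$cohort[!pd, CONFOUNDS]),
    mask = select_features(resid_pd, co$cohort[pd, SCORES], alpha = 0.01)
  )
}

rebuild_biotypes <- function(co = rebuild_cohort(), sel = NULL) {
  if (is.null(sel)) sel <- rebuild_selection(co)
  X <- sel$resid_pd[, sel$mask$union, drop = FALSE]
  pca <- pca_reduce(X, var_target = 0.90)
  pick <- select_k(pca$scores, k_range = 2:10)
  assignment <- pick$assignment
  msig <- tapply(rowMeans(X), assignment$labels, mean)
  remap <- setNames(rank(msig, ties.method = "first"), names(msig))
  assignment$labels <- as.integer(remap[as.character(assignment$labels)])
  list(sel = sel, pca = pca, pick = pick, assignment = assignment)
}
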