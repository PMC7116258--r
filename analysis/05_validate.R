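# Stage 5 -- biotype validation.
#
# Three complementary checks of the discovered biotypes: voxelwise
# biotype-vs-control contrast maps under FDR q = 0.005, a baseline
# clinical comparison table (t after confound removal; chi-square for
# categorical variables; BH across the family), and a 10-fold
# cross-validated RBF-kernel SVM that diagnoses biotype from the
# union-mask voxels.

source(file.path("analysis", "00_config.R"))

co <- rebuild_cohort()
maps <- rebuild_smoothed(co)
bt <- rebuild_biotypes(co)
pd <- co$cohort$group == "PD"
covars <- co$cohort[, CONFOUNDS]

for (b in 1:2) {
  in_b <- which(pd)[bt$assignment$labels == b]
  cm <- voxelwise_group_ttest(maps[in_b, , drop = FALSE],
                              maps[!pd, , drop = FALSE],
                              covariates = covars[c(in_b, which(!pd)), ],
                              q = 0.005)
  sig_t <- cm$t[cm$mask]
  cat(sprintf(
    "biotype %d vs controls: %d significant voxels (q = 0.005), mean t = %+.2f\n",
    b, sum(cm$mask), if (length(sig_t)) mean(sig_t) else NA))
  write.csv(data.frame(voxel = which(cm$mask), t = cm$t[cm$mask],
                       p = cm$p[cm$mask]),
            file.path(RESULTS_DIR, sprintf("contrast_biotype%d.csv", b)),
            row.names = FALSE)
}

tab <- baseline_comparison(co$cohort[pd, ], bt$assignment$labels,
                           continuous = c("age", "education", SCORES),
                           categorical = c("sex", "race"))
write.csv(tab, file.path(RESULTS_DIR, "baseline_comparison.csv"),
          row.names = FALSE)
cat("\nBaseline variables differing between biotypes after FDR:\n")
print(tab[tab$significant, c("variable", "statistic", "p", "p_adj")],
      row.names = FALSE)

metrics <- crossval_svm(bt$sel$resid_pd[, bt$sel$mask$union, drop = FALSE],
                        bt$assignment$labels, folds = 10,
                        seed = MASTER_SEED + 2L, positive = "1")
print(metrics)
write.csv(data.frame(metric = c("accuracy", "sensitivity", "specificity", "auc"),
                     value = c(metrics$accuracy, metrics$sensitivity,
                               metrics$specificity, metrics$auc)),
          file.path(RESULTS_DIR, "classifier_metrics.csv"), row.names = FALSE)
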