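# Stage 6 -- longitudinal progression contrasts.
#
# Joins the discovered biotype labels onto the longitudinal table and
# fits, per outcome, a linear mixed model with biotype x time fixed
# effects, confound fixed effects, and correlated per-subject random
# intercepts and slopes (REML). The biotype x time coefficient is the
# between-biotype difference in monthly progression; BH-FDR is applied
# across the six outcomes.

source(file.path("analysis", "00_config.R"))

cfg <- study_config()
co <- rebuild_cohort()
long <- simulate_longitudinal(cfg, co$truth, co$cohort)
bt <- rebuild_biotypes(co)

pd_ids <- rownames(co$maps)[co$cohort$group == "PD"]
discovered <- setNames(bt$assignment$labels, pd_ids)
long$biotype <- discovered[long$subject_id]

ps <- progression_summary(long, q = 0.05)
write.csv(as.data.frame(ps), file.path(RESULTS_DIR, "progression_summary.csv"),
          row.names = FALSE)

cat("Per-outcome biotype x time contrasts (per month):\n")
print(as.data.frame(ps)[, c("outcome", "beta_interaction", "se", "p",
                            "p_adj", "significant", "faster_biotype")],
      row.names = FALSE)
sig <- ps[ps$significant, ]
cat(sprintf("\n%d of %d outcomes progress at different rates after FDR;\n",
            nrow(sig), nrow(ps)))
cat(sprintf("the faster-declining group is biotype %s (smaller subcortical volumes)\n",
            paste(unique(sig$faster_biotype), collapse = "/")))
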