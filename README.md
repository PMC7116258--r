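# pdbiotype

Neuroanatomic biotype discovery and progression modelling for early
Parkinson disease (PD).

Patients with newly diagnosed PD look clinically similar but progress
at very different rates. `pdbiotype` implements, as a tested and fully
reproducible R pipeline, the hypothesis that this heterogeneity has a
measurable anatomic substrate: patient subgroups ("biotypes") defined
by shared patterns of local brain volume, detectable at diagnosis from
structural MRI and predictive of subsequent decline. It is written for
neuroimaging statisticians and methods researchers who want to study,
stress-test or extend this class of subtyping analysis without access
to controlled patient data: every stage runs on a seeded synthetic
cohort generator with planted ground truth.

## The pipeline

1. **Deformation-based morphometry (DBM).** Local volume at voxel *x*
   is the Jacobian determinant det(I + ∇u(x)) of the displacement
   field *u* aligning the template to the subject (det > 1 = locally
   larger than template), smoothed with a Gaussian kernel of fixed
   FWHM (default 8 mm; σ = FWHM / (2√(2 ln 2))).
2. **Symptom-correlated voxel selection.** After regressing age, sex,
   education, race and site out of the voxel values (fitted within
   patients), voxels with Spearman p < 0.01 (uncorrected) against any
   of the six baseline severity scores — MDS-UPDRS I, II, III, total,
   tremor, PIGD — form the feature union.
3. **Biotyping.** PCA to 90% explained variance; Ward linkage on
   patient-by-patient correlation distance d(i,j) = 1 − r(xᵢ, xⱼ);
   cluster number by the Calinski–Harabasz criterion
   CH = [B/(k−1)] / [W/(n−k)]; stability vs k-means by Cohen's κ.
4. **Validation.** Voxelwise biotype-vs-control t contrasts under
   Benjamini–Hochberg FDR (q = 0.005), a baseline comparison table,
   and a 10-fold cross-validated RBF-kernel SVM diagnosing biotype
   from the selected voxels.
5. **Progression.** Per outcome y, the linear mixed model
   y_it = β₀ + β_b·bio_i + β_t·t + β_int·(bio_i × t) + covariates
   + b₀ᵢ + b₁ᵢ·t + ε, REML-fitted with correlated random
   intercepts/slopes; β_int is the between-biotype progression
   contrast per month, BH-adjusted across outcomes.

## Worked example

```r
library(pdbiotype)
cfg <- pipeline_config(seed = 42, n_pd = 120, n_hc = 60)
res <- run_pipeline(cfg)
print(res)
```

```
pdbiotype pipeline run
  cohort: 120 PD / 60 HC on a 24x24x24 grid
  selected voxels (union): 1753
  biotypes: k = 2 (1: 44 [36.67%], 2: 76 [63.33%]), kappa vs k-means 1.00
  classifier: accuracy 100.0%, AUC 1.00
  progression: 5/6 outcomes differ after FDR (pigd, updrs_total, updrs1, updrs2, updrs3)
```

Reading this output: the generator planted two biotypes (44 and 76 of
120 patients) as a ±0.8 SD mean shift of a central "subcortical" block,
with clinical scores linked to that signal. The screen found 1,753
symptom-correlated voxels; Ward clustering on their principal
components chose k = 2 and recovered the planted split exactly (the
36.67%/63.33% shares are the planted 44/76), in perfect agreement with
k-means (κ = 1). The SVM separates the two biotypes from the voxel
features, and the mixed models flag faster decline in biotype 1 — the
smaller-volume group — on every score except tremor, whose planted
slopes are equal. On real data the effect is far subtler; the synthetic
defaults are chosen so recovery is reliable but not trivial (see the
methods vignette in `vignettes/`).

The `analysis/` directory exposes the same run as numbered stage
scripts (`01_simulate.R` … `06_progression.R`), each writing its tables
under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/04_biotype.R   # PCA, Ward + CH, kappa, shares
```

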