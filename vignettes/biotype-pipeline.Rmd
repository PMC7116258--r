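---
title: "Neuroanatomic biotyping of early Parkinson disease: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuroanatomic biotyping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Early Parkinson disease is clinically heterogeneous: patients with
indistinguishable presentations progress at very different rates. One
hypothesis is that this heterogeneity has a neuroanatomic substrate —
*biotypes* defined by shared patterns of regional brain volume rather
than by symptoms — and that those biotypes, measurable at diagnosis,
predict the subsequent course. `pdbiotype` implements a complete,
testable pipeline for that idea:

1. **Morphometry.** Per-voxel local volume is estimated by
   deformation-based morphometry (DBM): the Jacobian determinant of the
   nonlinear displacement field aligning a brain to a template, smoothed
   with a Gaussian kernel of fixed FWHM.
2. **Feature selection.** Voxels whose confound-adjusted DBM values
   correlate with any of six baseline clinical severity scores
   (MDS-UPDRS I, II, III, total, tremor, PIGD) by Spearman rank
   correlation at p < 0.01, uncorrected, form the feature set.
3. **Biotyping.** The selected voxels are reduced by PCA to the smallest
   component set explaining 90% of the variance; patients are clustered
   by Ward linkage on pairwise correlation distance; the cluster number
   is chosen by the Calinski–Harabasz criterion; stability is quantified
   by Cohen's kappa against best-of-50 k-means.
4. **Validation.** Voxelwise biotype-vs-control t contrasts under
   Benjamini–Hochberg FDR, a baseline clinical comparison table, and a
   10-fold cross-validated Gaussian-kernel SVM that diagnoses biotype
   from the selected voxels.
5. **Progression.** Per outcome, a linear mixed model with biotype,
   time (months), their interaction and demographic covariates as fixed
   effects and correlated per-subject random intercepts and slopes
   (REML); the biotype-by-time coefficient is the progression contrast,
   FDR-adjusted across outcomes.

Because the clinical data this design targets sit behind a controlled
access agreement, every stage is exercised on a **synthetic cohort
generator** with planted ground truth; the generator is itself a
first-class, tested module.

## Conventions and key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fwhm_mm` | 8 | smoothing kernel FWHM; sigma = FWHM / (2 sqrt(2 ln 2)) |
| `alpha` | 0.01 | per-voxel, per-score Spearman screen level, uncorrected |
| `var_target` | 0.90 | cumulative explained-variance target for PCA |
| `k_range` | 2..10 | candidate cluster numbers for Calinski–Harabasz |
| `folds` | 10 | stratified CV folds for the classifier |
| `q_map` | 0.005 | FDR level of the voxelwise contrast maps |
| `q_table`, `q_progress` | 0.05 | FDR levels of the baseline table and the progression summary |

**Direction convention (stated once, used everywhere).** The
displacement field maps template coordinates to subject coordinates, so
`det(I + grad u) > 1` means the subject is locally *larger* than the
template. Biotype 1 is, by construction of the report ordering, the
cluster with the lower mean selected-voxel DBM signal — the
"contraction" biotype with smaller subcortical volumes — and biotype 2
the "expansion" biotype. Whether the affine part of a warp should
contribute to the determinant is left to the caller: the map is computed
for the field as supplied.

**Uncorrected selection is deliberate.** The screen's purpose is to
hand clustering a permissive, symptom-linked feature set, not to make
voxelwise inference; multiplicity control at this stage would starve
the clustering of features. A BH-corrected screen is available via
`select_features(..., adjust = "BH")` for sensitivity analyses.

**Ward on correlation distance is a heuristic.** Ward's variance
argument assumes squared Euclidean dissimilarities; applying the
Lance–Williams Ward update to correlation distances is the field's
standard recipe for patient subtyping and is reproduced as such
(`stats::hclust(method = "ward.D")` on the supplied dissimilarities).
`ward_cluster_euclidean()` provides the formally clean alternative
(Euclidean `ward.D2` on row-standardized scores) for sensitivity
checks. The Calinski–Harabasz index is computed with Euclidean geometry
in PCA score space even though the tree was built on correlation
distance — it is a variance-ratio criterion and has no
correlation-distance analogue.

**PCA columns are centred, not standardized.** The voxel values are
residuals on a common scale, so covariance PCA is the natural choice;
`pca_reduce(..., scale. = TRUE)` exposes the standardized variant.

**Residualization is fitted within patients.** Confound coefficients
(age, sex, education, race, site) are estimated on the PD subjects only
— selection happens within patients — and controls are projected with
the patient-fitted coefficients when the two groups are later compared
(`residualize_apply()`).

**Scores are not residualized by default.** The screen correlates
residualized voxels against *raw* scores. If scores carry covariate
structure (e.g. an age trend), the screen becomes slightly
conservative: the shared covariate direction is projected out of the
voxels, shrinking the null correlation variance by the score's
confound R². `select_features(..., covariates = )` residualizes the
scores as well, restoring exact calibration; both behaviours are
tested.

## The synthetic cohort generator

`simulation_config()` defaults describe the cohort the pipeline is
sized for: 314 patients split 36.31%/63.69% across two biotypes, 143
controls, age 61 ± 9.5 years, 34.1% women, five sites, and 13 visits
over five years (baseline, quarterly during year one, six-monthly
thereafter). Each subject's map is baseline 1 plus unit-variance voxel
noise, additive site offsets (N(0, 0.1²)), a small age slope (−0.01 per
year) and sex offset (0.05); patients receive a mean shift of
±`effect_size` (in voxel-noise SD units; default 0.8) inside a central
"subcortical" block — negative for biotype 1, positive for biotype 2,
zero for controls. Clinical scores are linear in the subject's mean
planted-block signal (negative link: smaller volumes, worse severity)
plus an age term and Gaussian noise, so voxel–score correlations exist
by construction; the tremor link is the weakest, mirroring its looser
coupling to the anatomic signal. Longitudinal outcomes follow
subject-specific lines with biotype-specific monthly slopes (biotype 1
faster on every score except tremor, where the slopes are equal),
correlated random intercepts/slopes (SDs 2 and 0.1, correlation 0) and
unit residual noise.

The fraction-to-count allocation uses largest-remainder rounding
followed by a seeded permutation, so cluster sizes are exact and
assignment is random; sites are assigned round-robin over a seeded
subject permutation. Everything is bit-reproducible from the single
config seed, from which each stage derives its own sub-seed.

What the generator does **not** emulate: raw T1 intensities, bias
fields, registration failure, spatially structured (autocorrelated)
voxel noise, anatomically shaped effect regions, non-Gaussian score
distributions, floor effects in rating scales, or informative dropout.
Passing tests therefore demonstrate that the pipeline recovers the
structure this model plants at realistic sizes and noise levels — not
that it would recover biotypes from any particular real cohort.

## Numerical choices

- **Gradients**: central differences on interior voxels, one-sided at
  the boundary, components scaled by voxel spacing; the determinant is
  an explicit 3×3 cofactor expansion. On affine fields the scheme is
  exact everywhere (differences of a linear field are exact).
- **Smoothing kernel**: truncated at 4 sigma and renormalized to unit
  sum; boundary rows renormalize over the surviving support, so a
  constant image is reproduced exactly and edges are not deflated
  toward zero. Mass is conserved wherever the kernel support is fully
  interior.
- **Spearman p-values**: two-sided t approximation
  t = rho sqrt((n−2)/(1−rho²)), accurate in the n ≈ 300 regime the
  screen runs in; mid-ranks for ties; |rho| = 1 returns p = 0.
- **Degenerate inputs**: constant vectors are refused by the
  correlation routines with the offending subject named; zero-variance
  voxels become NA in contrast maps and leave the FDR family; scores
  with fewer than 10 complete cases abort selection.
- **k-means**: Lloyd iterations from 50 seeded random starts;
  an initialization that collapses to an empty cluster is re-seeded;
  the lowest within-SS run is returned together with all per-start
  objectives.
- **Kappa label alignment**: cluster labels carry no meaning across
  methods, so the k-means labelling is re-mapped by the agreement-
  maximizing permutation (exhaustive; k ≤ 7) before Cohen's kappa.
- **Mixed models**: REML via `lme4`; Wald z tests on fixed effects
  (a Satterthwaite refinement is a possible extension); a singular
  random-effect covariance triggers an annotated refit with
  uncorrelated random effects; non-convergence is flagged in the
  result, never silent. Site enters as fixed-effect dummies.
- **Ties in agglomeration** follow `hclust`'s deterministic policy, so
  identical inputs always give identical trees.

## Problem sizes in the test suite

The suite exercises the pipeline at deliberately desk-scale sizes: a
24³ grid (the full-resolution MNI grid is emulated, not reproduced),
cohorts of 60–300 patients, 20-seed Monte-Carlo loops for the
calibration and recovery properties, and 200 scaled-down replicates
(40 subjects per biotype, 13 visits) for the mixed-model coverage
check. The complete end-to-end run — simulate, smooth, select, cluster,
validate, progression — takes well under a minute on one CPU at these
sizes.

## Known limitations

- Registration, segmentation, bias correction and template
  construction are upstream of this package: it consumes displacement
  fields or DBM maps (NIfTI-1), it does not produce them from images.
- Biotype membership is discrete; continuous membership probabilities
  and consensus/bootstrapped stability curves are out of scope.
- The classifier deliberately replicates the design in which feature
  selection precedes cross-validation on the full sample (selection
  leakage by construction); `crossval_svm_nested()` re-runs
  residualization and selection inside every training fold so the two
  estimates can be reported side by side.
- The paper-facing choice of which class "sensitivity" refers to is a
  convention; here the positive class defaults to the minority
  (contraction) biotype and is configurable.
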