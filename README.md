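# simonfmri

Simulation and analysis of event-related Simon-task fMRI studies of
cognitive conflict, built around a two-group design (stuttering vs fluent
control speakers). The package provides, as tested and reusable R code, the
full analysis chain such a study needs:

- **Sequence-dependent trial coding.** Each trial is labelled by the
  congruency of the preceding and current stimulus (cC, cI, iC, iI);
  errors, omissions, RT outliers and run-initial trials become regressors
  of no interest. The two effects of interest are the contrasts
  **cI − cC** (conflict resolution) and **iI − cI** (context-dependent
  adaptation, the Gratton effect).
- **Behavioral inference.** 2 (preceding) × 2 (current) × 2 (group)
  mixed-design ANOVA on condition mean RTs with partial η², the iI-vs-cI
  paired t post-hoc, and group accuracy tests.
- **First-level GLM.** Canonical double-gamma HRF convolution of 1300 ms
  stimulus boxcars, per-run discrete-cosine high-pass confounds (1/128 Hz),
  per-voxel OLS, contrast maps.
- **Group inference.** Per-voxel ANCOVA (group + age + sex + IQ +
  RT interference), within-group severity correlation, and Monte-Carlo
  cluster-extent familywise correction: null smooth Gaussian fields are
  thresholded two-sided at voxel p < 0.025 and the smallest cluster extent
  k\* with P(max cluster ≥ k\*) ≤ 0.05 is derived by simulation.
- **Effective connectivity.** Seed-sphere time series (8 mm spheres at the
  ACC and four DLPFC foci) and bivariate Granger Causality Indices,
  GCI(A→B) = 1 − var(e_AB)/var(e_B) from nested lag-p autoregressions, with
  Bonferroni-adjusted within-group tests and rank-sum z between groups.
- **A synthetic-cohort generator** (trial sequences, behavior, 4D BOLD with
  planted regional effects, covariates, severity coupling) so every stage
  is testable end-to-end with known ground truth and no data download.

Data objects are S4 (`TaskDesign`, `AcquisitionGrid`, `EffectTemplate`,
`HRFSpec`, `DesignMatrix`, `GLMFit`, `StatMap`) with validity checks and
accessors; 4D volumes are written and read as NIfTI-1 via RNifti, events
and participants as BIDS-style TSV.

## Worked example

A desk-scale end-to-end run — 6 + 6 subjects, one imaging run each, a
16 × 16 × 8 frontal grid — takes a few seconds:

```r
library(simonfmri)
cfg <- defaultPipelineConfig(nStutter = 6, nControl = 6, nRunsImaging = 1)
cfg$grid$dims <- c(16L, 16L, 8L)
cfg$group$nIter <- 100
res <- runPipeline(cfg, outDir = "out1", seed = 7)
res$anova
```

```
         effect            F df_num df_den            p partial_eta_sq
1         group  0.006287645      1     10 9.383626e-01   0.0006283694
2           pre 15.259282457      1     10 2.930783e-03   0.6041059354
3     pre:group  0.472709868      1     10 5.073756e-01   0.0451373020
4           cur 85.138717346      1     10 3.305687e-06   0.8948903214
5     cur:group  0.145249529      1     10 7.110889e-01   0.0143169992
6       pre:cur 24.853794890      1     10 5.490646e-04   0.7130871966
7 pre:cur:group  0.141593063      1     10 7.145629e-01   0.0139616195
```

Even at n = 12 the planted behavioral effects come out: responses are
slower to incongruent stimuli (`cur`, F₁,₁₀ = 85.1, p < 0.01) and the
interference shrinks after a preceding incongruent trial (`pre:cur`,
F₁,₁₀ = 24.9, p < 0.01), while nothing involving diagnosis is significant —
the generator plants no group difference by default. `res$kStar` (17 here)
is the Monte-Carlo cluster-extent threshold for this grid and mask;
`res$clusterTables` holds the corrected group-difference clusters (empty
under the default null), and `res$gciReport` the Table-style connectivity
summary, e.g.:

```
        direction stutter_mean control_mean         z p_between
1 ACC->DLPFC_BA46      0.00790      0.00203  1.601282   0.10931
2 DLPFC_BA46->ACC      0.00095      0.00429 -1.120897   0.26233
```

Small positive GCIs with no group difference are exactly what independent
noise plus in-sample autoregression bias produce. The output directory
contains the same results as TSV/JSON plus group statistic maps as
`.nii.gz`, and a manifest with the seed and config hash.

To plant effects, set e.g.
`cfg$cohortParams$effects$groupDelta <- c(cC=0, cI=0.35, iC=0, iI=0)`
(a stutterer-specific conflict difference) or
`cfg$cohortParams$effects$severityBeta <- -0.3` (severity coupling); the
methods vignette (`vignettes/simonfmri-methods.Rmd`) documents every
parameter, the model assumptions and the design decisions.

A thin CLI over the same functions is in `inst/scripts/run_pipeline.R`
(`simulate` and `run-all` verbs, `--config`/`--out`/`--seed`).

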