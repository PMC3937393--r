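---
title: "Methods: simulation and analysis of Simon-task fMRI conflict adaptation"
author: "simonfmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of Simon-task fMRI conflict adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`simonfmri` implements a complete analysis chain for event-related Simon-task
fMRI studies of cognitive conflict in a two-group (stuttering vs fluent
control) design, together with a synthetic-cohort generator that gives every
stage a known ground truth. The chain is:

1. **Task simulation** — pseudorandom, counterbalanced trial sequences with
   jittered inter-stimulus intervals.
2. **Behavior** — an additive reaction-time model producing the congruency
   (interference) effect and the sequence-adaptation (Gratton) effect.
3. **Sequence coding** — trials labelled cC/cI/iC/iI by the congruency of the
   preceding and current stimulus; errors, omissions, RT outliers and
   run-initial trials become no-interest regressors.
4. **First level** — per-voxel OLS on HRF-convolved condition regressors with
   discrete-cosine high-pass confounds; contrasts cI − cC (conflict
   resolution) and iI − cI (context-dependent adaptation).
5. **Group level** — covariate-adjusted two-sample inference, within-group
   severity correlation, and Monte-Carlo cluster-extent familywise
   correction.
6. **Connectivity** — seed-sphere Granger Causality Indices
   (GCI = 1 − var(eAB)/var(eB)) with within- and between-group statistics.

# The synthetic cohort and what it emulates

The generator's defaults encode the study conditions: three runs of 44
trials (22 congruent, 22 incongruent, direction/position counterbalanced),
1300 ms stimuli, ISIs uniform on 4000–7000 ms, TR 2200 ms, 140 volumes per
run (308 s per run, 924 s in total); 46 stutterers and 52 controls with ages
24.0 ± 11.0 / 23.1 ± 11.5 years, 63%/64% male, and WASI IQ means 108.2 /
115.5. The published IQ dispersions (±2.11 / ±2.10) are standard errors, not
SDs; the generator converts them (SD = SEM·√N ≈ 14.3 / 15.1). Stutterers
receive a standard-normal severity z-score (controls: missing), a 22%
medication rate and a 5/46 comorbidity rate.

Reaction times follow
`rt = base + interference·[incongruent] − adaptation·[iI] + N(0, sd)`,
with per-subject parameters drawn around 60 ms interference, 25 ms
adaptation and 40 ms trial noise, and a 5% error rate. This is the simplest
generative model that reproduces the reported pattern (congruency main
effect, preceding × current interaction, iI faster than cI); it makes no
claim about RT distribution shape (no ex-Gaussian tail), post-error slowing,
or speed–accuracy trade-offs.

BOLD data follow a linear forward model: spherical regions tied to
conditions (by default all four conditions at the medial-frontal/ACC
coordinate −6, 28, 31) carry amplitude × HRF-convolved regressor; noise is
temporally AR(1) (coefficient 0.3), spatially smoothed to 8 mm FWHM, scaled
to unit marginal SD. Because the generator and the fitter share the same
convolution, noiseless simulations are recovered exactly — that closure is a
correctness check of the estimator, not evidence about real data, where HRF
mismatch, motion, and physiological noise (all outside this model) dominate.

**ISI schedules.** Jitter is uniform on the stated range; schedules are
rejection-sampled so the trial train fits the 308 s run. This conditions the
realised ISI distribution slightly (the reported realised mean, 5372 ms, is
below the uniform midpoint 5500 ms, consistent with some form of
fit-conditioning in the original schedule whose exact rule is unknown; the
generator does not attempt to match 5372 ms).

**Seeding.** Every stage draws from a seed derived from (global seed, stage
name, unit index) by a fixed modular mix, so cohorts are pure functions of
(parameters, seed) and enlarging a cohort never changes existing subjects.

# Sequence coding decisions

The condition of a trial is determined by the *stimulus* congruency of the
preceding trial regardless of whether that trial was answered correctly: the
stimulus, not the response, carries the conflict context. Run-initial trials
get their own no-interest regressor rather than being dropped — they occupy
BOLD variance. The RT outlier rule (no published definition exists) defaults
to a 200 ms floor and a subject mean + 3 SD ceiling computed over correct
trials, both configurable; with fewer than three correct trials the ceiling
is skipped with a warning.

# Behavioral inference

The 2 × 2 × group ANOVA runs on per-subject condition means (consistent with
the reported denominator df of 96 at N = 98), via `aov` with
`Error(subject/(pre*cur))` strata; with two-level within factors sphericity
is not at issue. Partial η² is df·F/(df·F + df_err). The test suite checks
the F statistics against an independent stratum-wise projection oracle
(difference scores regressed on group) to 1e-8. A stratum whose total sum of
squares is numerical dust (identical cell means) is reported as F = 0 rather
than a ratio of rounding errors. The adaptation post-hoc is a paired t (iI
vs cI, pooled groups, df = N − 1); accuracy is compared between groups with
pooled-variance two-sample t-tests (df = N − 2).

# First-level model

The canonical HRF is the conventional double-gamma (delays 6 and 16 s, unit
dispersions, undershoot ratio 1/6, 32 s support, 0.1 s sampling),
**normalised to unit peak** so that fitted amplitudes are in the signal
units of the planted effects. Events are modelled as 1300 ms boxcars (the
stimulus duration), convolved at 0.1 s resolution and sampled at volume
onsets. Runs are concatenated with run-specific regressors and constants.
High-pass filtering (cutoff 128 s) is implemented by *including* the
per-run discrete-cosine basis (K = ⌊2T/cutoff⌋ = 4 components at 308 s) as
confounds rather than pre-filtering, keeping degrees of freedom explicit.
Note the finite-window caveat: drifts at DCT frequencies are removed
exactly, but an off-basis slow sinusoid retains 5–20% of its RMS as
leakage — true of any DCT high-pass of this order. No prewhitening is
applied: group inference is random effects on contrast maps, which is robust
to first-level variance misspecification; the AR(1) noise therefore slightly
miscalibrates *first-level* (never group-level) standard errors.

# Group level

Group maps come from the per-voxel ANCOVA
`contrast ~ intercept + group + age + sex + IQ + RT-interference` with
sex coded 0/1 and no interactions; t is the group coefficient over its
standard error (df = N − 6). The severity analysis is the voxelwise Pearson
correlation between stutterers' contrast estimates and severity z-scores,
unadjusted by default (the original covariate treatment is unstated), with
an adjusted mode available.

Cluster-extent correction is Monte-Carlo: white noise on the grid, smoothed
to the nominal applied FWHM (8 mm — synthetic data have known smoothness, so
residual-based smoothness estimation is unnecessary and off by default),
masked, standardised, thresholded two-sided at voxel p < 0.025
(|z| > 2.24), and the maximum cluster size under 18-connectivity recorded
per iteration; k* is the smallest extent with exceedance probability ≤ 0.05.
Real statistic maps are thresholded the same way with Student-t quantiles
and clustered separately by sign. Design choices here: the two-sided
threshold with direction-separated reporting reproduces signed
hyper-/hypo-activation tables; 18-connectivity is the common neuroimaging
convention (6 and 26 available); the default mask is an axis-aligned
ellipsoid at 15/16 of the grid half-dimensions, ~60,000 voxels on the
64 × 64 × 34 acquisition matrix — a deliberately transparent stand-in for a
brain mask. The resulting k* is strongly mask- and smoothness-dependent,
which is why the mask is an explicit input; the held-out familywise-error
self-check (applying the derived (p, k*) pair to fresh nulls) is the part of
the calibration that is mask-independent and should always hold.

# Connectivity

ROI series are the mean over voxels whose centres lie within 8 mm of the
seed (ACC −6, 28, 31; DLPFC BA46/44/8/45 at the reported foci), demeaned and
linearly detrended per run. GCI uses nested OLS autoregressions of order 1
by default — at TR 2.2 s with 140 volumes, higher orders are weakly
identified; an information-criterion option exists in the AR order argument.
Runs are fitted separately and indices averaged (concatenation would create
spurious lag-1 transitions). In-sample nested least squares guarantees
0 ≤ GCI < 1; a perfectly predictable target returns 1 with a flag. Within
groups, indices are tested against zero by one-sample t with Bonferroni
adjustment over the 8 directed pairs; between groups, a tie-corrected
rank-sum statistic standardised to z (the original's exact test is unnamed;
these are explicit substitutes, not claims about it). GCI is computed on raw
demeaned/detrended series; task-evoked signal common to both ROIs can
inflate both directions equally, which is one reason between-group
differences, not absolute values, are the interpretable quantity.

# Pipeline and reproducibility

`runPipeline()` executes all stages from one configuration and writes the
behavioral reports, cluster tables, severity table, GCI report, group-level
NIfTI maps, the cluster-correction calibration, and a manifest (seed, config
hash, package version). Stages hand off in memory — per-subject 4D volumes
are transient by design; `writeBoldNifti()`/`writeEventsTsv()` and the
`simulate` verb of the bundled script persist them when a file-based
workflow is wanted. The `nRunsImaging` option (default 1) bounds the BOLD
simulation cost; behavioral analysis always uses all runs.

# Problem sizes used by the test suite

The packaged experiments are sized for a single CPU: unit tests use desk
grids (8³–16³ voxels); the cluster-correction calibration runs 1000
iterations on the full 64 × 64 × 34 grid; the end-to-end selectivity
experiment uses 20 cohorts of 46 + 52 subjects on a 16 × 16 × 10 frontal
grid (origin MNI −20, 20, 25, chosen so the ACC and DLPFC coordinates fall
inside) with one imaging run per subject; the severity-recovery experiment
uses 10 cohorts of 46 stutterers with coupling β = −0.3. The planted group
difference in the selectivity experiment is Δ = 0.35 signal units on the cI
amplitude, i.e. d ≈ 0.8 against the total per-subject contrast SD at the
seeded region (√2·0.25 between-subject amplitude SD plus ≈0.26 first-level
estimation error under the default noise model).

# Known limitations

- No physiological noise, motion, susceptibility artifacts, or HRF
  variability: recovery results certify the estimator chain, not robustness
  to real-data confounds.
- The brain mask is a geometric ellipsoid; anatomical masks change the
  cluster-extent threshold and are supplied by the user in real-data use.
- Cluster peaks are reported as MNI coordinates only; no anatomical
  labelling.
- The behavioral model is additive Gaussian; distributional RT analyses are
  out of scope.
- Real-data mode consumes already-preprocessed NIfTI volumes; realignment,
  slice-timing, normalisation and smoothing of raw scans are out of scope.
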