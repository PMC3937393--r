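#' @import methods
NULL

# ---- TaskDesign -------------------------------------------------------------

#' TaskDesign: timing and composition of the event-related Simon task
#'
#' Describes one acquisition protocol: number of runs, trial composition per
#' run, stimulus duration, the jittered inter-stimulus-interval range, the
#' repetition time and the number of volumes per run. Defaults reproduce a
#' three-run design with 44 trials per run (22 congruent, 22 incongruent),
#' 1300 ms stimuli, 4000-7000 ms uniform ISI jitter, TR 2200 ms and 140
#' volumes per run (308 s per run, 924 s in total).
#'
#' @slot nRuns integer, number of runs.
#' @slot trialsPerRun integer, trials in each run.
#' @slot nCongruentPerRun,nIncongruentPerRun integer, per-run composition.
#' @slot stimDurationMs numeric, stimulus duration in ms.
#' @slot isiMinMs,isiMaxMs numeric, uniform ISI jitter range in ms.
#' @slot trMs numeric, repetition time in ms.
#' @slot volumesPerRun integer, volumes acquired per run.
#' @exportClass TaskDesign
setClass("TaskDesign",
  representation(nRuns = "integer", trialsPerRun = "integer",
    nCongruentPerRun = "integer", nIncongruentPerRun = "integer",
    stimDurationMs = "numeric", isiMinMs = "numeric", isiMaxMs = "numeric",
    trMs = "numeric", volumesPerRun = "integer"))

setValidity("TaskDesign", function(object) {
  msg <- character()
  if (object@trialsPerRun != object@nCongruentPerRun + object@nIncongruentPerRun)
    msg <- c(msg, "trialsPerRun must equal nCongruentPerRun + nIncongruentPerRun")
  if (object@isiMinMs > object@isiMaxMs)
    msg <- c(msg, "isiMinMs must not exceed isiMaxMs")
  if (any(c(object@nRuns, object@trialsPerRun, object@volumesPerRun) < 1L))
    msg <- c(msg, "nRuns, trialsPerRun and volumesPerRun must be positive")
  if (object@stimDurationMs <= 0 || object@trMs <= 0)
    msg <- c(msg, "stimDurationMs and trMs must be positive")
  # even with minimal jitter the trial train must fit into the run
  minimal <- object@trialsPerRun * object@stimDurationMs +
    object@trialsPerRun * object@isiMinMs
  if (minimal > object@trMs * object@volumesPerRun)
    msg <- c(msg, sprintf(
      "task cannot fit in the run: %d trials need >= %.0f ms but the run lasts %.0f ms",
      object@trialsPerRun, minimal, object@trMs * object@volumesPerRun))
  if (length(msg)) msg else TRUE
})

#' Construct a TaskDesign
#'
#' @param nRuns,trialsPerRun,nCongruentPerRun,nIncongruentPerRun Trial
#'   composition; defaults 3 runs of 22 + 22.
#' @param stimDurationMs Stimulus duration (ms), default 1300.
#' @param isiMinMs,isiMaxMs Uniform ISI jitter range (ms), default 4000-7000.
#' @param trMs Repetition time (ms), default 2200.
#' @param volumesPerRun Volumes per run, default 140.
#' @return A [TaskDesign-class] object.
#' @export
#' @examples
#' d <- taskDesign()
#' runDurationS(d)   # 308 s
taskDesign <- function(nRuns = 3L, trialsPerRun = 44L,
                       nCongruentPerRun = 22L, nIncongruentPerRun = 22L,
                       stimDurationMs = 1300, isiMinMs = 4000,
                       isiMaxMs = 7000, trMs = 2200, volumesPerRun = 140L) {
  new("TaskDesign", nRuns = as.integer(nRuns),
      trialsPerRun = as.integer(trialsPerRun),
      nCongruentPerRun = as.integer(nCongruentPerRun),
      nIncongruentPerRun = as.integer(nIncongruentPerRun),
      stimDurationMs = stimDurationMs, isiMinMs = isiMinMs,
      isiMaxMs = isiMaxMs, trMs = trMs,
      volumesPerRun = as.integer(volumesPerRun))
}

# ---- AcquisitionGrid --------------------------------------------------------

#' AcquisitionGrid: voxel lattice and its mapping to MNI millimetres
#'
#' A 3D voxel grid with an RAS+ affine mapping 1-based voxel indices to MNI
#' millimetre coordinates; the grid centre maps to a configurable origin.
#'
#' @slot dims integer(3), voxel counts.
#' @slot voxelSizeMm numeric(3), voxel edge lengths in mm.
#' @slot affine 4x4 matrix mapping (i, j, k, 1) to (x, y, z, 1) in mm.
#' @slot trMs numeric, repetition time in ms.
#' @exportClass AcquisitionGrid
setClass("AcquisitionGrid",
  representation(dims = "integer", voxelSizeMm = "numeric",
                 affine = "matrix", trMs = "numeric"))

setValidity("AcquisitionGrid", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be three positive voxel counts")
  if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
    msg <- c(msg, "voxelSizeMm must be three positive lengths")
  if (!all(dim(object@affine) == c(4L, 4L)) ||
      abs(det(object@affine)) < .Machine$double.eps)
    msg <- c(msg, "affine must be an invertible 4x4 matrix")
  if (length(msg)) msg else TRUE
})

#' Construct an AcquisitionGrid
#'
#' @param dims Voxel counts, length 3.
#' @param voxelSizeMm Voxel sizes in mm, length 3; default c(3.75, 3.75, 3.5).
#' @param originMm MNI mm coordinate of the grid centre, default c(0, 0, 0).
#' @param trMs Repetition time in ms, default 2200.
#' @return An [AcquisitionGrid-class] object.
#' @details `defaultGrid()` gives the desk-scale 24 x 24 x 12 grid used
#'   throughout the examples and tests; it is centred on the left-frontal
#'   volume (origin MNI -20, 20, 25) so the anterior-cingulate and
#'   dorsolateral-prefrontal coordinates of interest fall inside it.
#'   `fullGrid()` reproduces the full acquisition matrix (64 x 64 in-plane,
#'   34 slices of 3.5 mm), centred to span the whole head.
#' @export
#' @examples
#' g <- defaultGrid()
#' voxelToMm(g, matrix(c(12, 12, 6), 1))
acquisitionGrid <- function(dims, voxelSizeMm = c(3.75, 3.75, 3.5),
                            originMm = c(0, 0, 0), trMs = 2200) {
  dims <- as.integer(dims)
  ctr <- (dims + 1) / 2
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(voxelSizeMm, 3)
  aff[1:3, 4] <- originMm - voxelSizeMm * ctr
  new("AcquisitionGrid", dims = dims, voxelSizeMm = voxelSizeMm,
      affine = aff, trMs = trMs)
}

#' @rdname acquisitionGrid
#' @export
defaultGrid <- function(trMs = 2200)
  acquisitionGrid(c(24L, 24L, 12L), originMm = c(-20, 20, 25), trMs = trMs)

#' @rdname acquisitionGrid
#' @export
fullGrid <- function(trMs = 2200)
  acquisitionGrid(c(64L, 64L, 34L), originMm = c(0, 0, 18), trMs = trMs)

# ---- EffectTemplate ---------------------------------------------------------

#' EffectTemplate: where condition-specific BOLD effects are planted
#'
#' A table of spherical regions, each tied to one trial condition, giving the
#' spatial layout of simulated activation. Per-subject amplitudes (from the
#' cohort profile) multiply the region `amplitude` factor.
#'
#' @slot regions data.frame with columns `name`, `x`, `y`, `z` (MNI mm),
#'   `radius_mm`, `condition`, `amplitude`.
#' @exportClass EffectTemplate
setClass("EffectTemplate", representation(regions = "data.frame"))

setValidity("EffectTemplate", function(object) {
  r <- object@regions
  need <- c("name", "x", "y", "z", "radius_mm", "condition", "amplitude")
  if (!all(need %in% names(r)))
    return(paste("regions must have columns:", paste(need, collapse = ", ")))
  if (nrow(r) && any(r$radius_mm <= 0)) return("radius_mm must be positive")
  ok <- c("cC", "cI", "iC", "iI", "run_initial", "nuisance")
  if (nrow(r) && !all(r$condition %in% ok))
    return(paste("unknown condition(s):",
                 paste(setdiff(r$condition, ok), collapse = ", ")))
  TRUE
})

#' Construct an EffectTemplate
#'
#' @param regions data.frame with columns `name`, `x`, `y`, `z`, `radius_mm`,
#'   `condition`, `amplitude`.
#' @return An [EffectTemplate-class] object.
#' @export
effectTemplate <- function(regions) {
  new("EffectTemplate", regions = as.data.frame(regions))
}

#' Default effect template: conflict and adaptation effects in the ACC
#'
#' Plants all four sequence conditions at a single medial-frontal site
#' (the reported ACC group-difference peak, MNI -6, 28, 31). The region
#' radius (default 12 mm) gives a planted extent of ~150 voxels at
#' 3.75 x 3.75 x 3.5 mm, comparable to the cluster sizes the analysis is
#' meant to detect. Per-condition amplitudes come from the cohort profiles;
#' the template `amplitude` column is a spatial gain factor (1 here).
#'
#' @param centerMm Region centre in MNI mm, default `c(-6, 28, 31)`.
#' @param radiusMm Sphere radius in mm, default 12.
#' @return An [EffectTemplate-class] object with one region per condition.
#' @export
defaultEffectTemplate <- function(centerMm = c(-6, 28, 31), radiusMm = 12) {
  conds <- c("cC", "cI", "iC", "iI")
  effectTemplate(data.frame(
    name = paste0("ACC_", conds),
    x = centerMm[1], y = centerMm[2], z = centerMm[3],
    radius_mm = radiusMm, condition = conds, amplitude = 1))
}

# ---- HRFSpec ----------------------------------------------------------------

#' HRFSpec: canonical double-gamma hemodynamic response parameters
#'
#' The conventional double-gamma kernel: a positive gamma-density main lobe
#' (peak near 5 s) minus a scaled gamma-density undershoot (peak near 15 s).
#' The kernel is normalised to unit peak so fitted amplitudes are in the
#' signal units of the planted effects.
#'
#' @slot peakDelayS,undershootDelayS numeric, gamma delays in s (6, 16).
#' @slot peakDispersionS,undershootDispersionS numeric, dispersions in s (1, 1).
#' @slot undershootRatio numeric, undershoot scale (1/6).
#' @slot kernelLengthS numeric, kernel support in s (32).
#' @slot dtS numeric, sampling step in s (0.1).
#' @exportClass HRFSpec
setClass("HRFSpec",
  representation(peakDelayS = "numeric", undershootDelayS = "numeric",
    peakDispersionS = "numeric", undershootDispersionS = "numeric",
    undershootRatio = "numeric", kernelLengthS = "numeric", dtS = "numeric"))

setValidity("HRFSpec", function(object) {
  vals <- c(object@peakDelayS, object@undershootDelayS, object@peakDispersionS,
            object@undershootDispersionS, object@kernelLengthS, object@dtS)
  if (any(vals <= 0)) return("all durations and dt must be positive")
  if (object@undershootRatio < 0) return("undershootRatio must be >= 0")
  TRUE
})

#' Construct an HRFSpec
#'
#' @param peakDelayS,undershootDelayS,peakDispersionS,undershootDispersionS
#'   Double-gamma parameters in seconds; defaults 6, 16, 1, 1.
#' @param undershootRatio Relative undershoot amplitude, default 1/6.
#' @param kernelLengthS Kernel support in seconds, default 32.
#' @param dtS Sampling step in seconds, default 0.1.
#' @return An [HRFSpec-class] object.
#' @export
hrfSpec <- function(peakDelayS = 6, undershootDelayS = 16,
                    peakDispersionS = 1, undershootDispersionS = 1,
                    undershootRatio = 1 / 6, kernelLengthS = 32, dtS = 0.1) {
  new("HRFSpec", peakDelayS = peakDelayS, undershootDelayS = undershootDelayS,
      peakDispersionS = peakDispersionS,
      undershootDispersionS = undershootDispersionS,
      undershootRatio = undershootRatio, kernelLengthS = kernelLengthS,
      dtS = dtS)
}

# ---- DesignMatrix -----------------------------------------------------------

#' DesignMatrix: time-by-regressor model for one subject
#'
#' Rows are volumes across concatenated runs; columns are HRF-convolved
#' condition regressors (per run), run-initial and nuisance regressors,
#' per-run discrete-cosine high-pass confounds and per-run constants.
#'
#' @slot values numeric matrix, volumes x regressors.
#' @slot trMs numeric, repetition time in ms.
#' @slot hpfCutoffS numeric, high-pass cutoff period in s.
#' @slot runIndex integer vector, run membership of each row.
#' @slot absent character, condition columns omitted because no events existed.
#' @exportClass DesignMatrix
setClass("DesignMatrix",
  representation(values = "matrix", trMs = "numeric", hpfCutoffS = "numeric",
                 runIndex = "integer", absent = "character"))

setValidity("DesignMatrix", function(object) {
  if (nrow(object@values) != length(object@runIndex))
    return("runIndex length must equal number of rows")
  if (is.null(colnames(object@values)))
    return("values must have column names")
  TRUE
})

# ---- GLMFit -----------------------------------------------------------------

#' GLMFit: per-voxel ordinary-least-squares estimates
#'
#' @slot beta numeric matrix, regressors x voxels.
#' @slot residVar numeric vector, per-voxel residual variance (RSS / dof).
#' @slot dof numeric, residual degrees of freedom (rows - rank).
#' @slot grid the [AcquisitionGrid-class] the voxels live on.
#' @exportClass GLMFit
setClass("GLMFit",
  representation(beta = "matrix", residVar = "numeric", dof = "numeric",
                 grid = "AcquisitionGrid"))

setValidity("GLMFit", function(object) {
  if (ncol(object@beta) != prod(object@grid@dims))
    return("beta columns must equal the number of grid voxels")
  if (any(object@residVar < -1e-12)) return("residVar must be non-negative")
  TRUE
})

# ---- StatMap ----------------------------------------------------------------

#' StatMap: a per-voxel statistic image
#'
#' @slot statistic 3D numeric array of t or r values.
#' @slot dof numeric, degrees of freedom of the statistic.
#' @slot kind character, `"group_t"`, `"severity_r"` or `"contrast"`.
#' @slot grid the [AcquisitionGrid-class].
#' @exportClass StatMap
setClass("StatMap",
  representation(statistic = "array", dof = "numeric", kind = "character",
                 grid = "AcquisitionGrid"))

setValidity("StatMap", function(object) {
  if (!all(dim(object@statistic) == object@grid@dims))
    return("statistic dimensions must match the grid")
  TRUE
})

statMap <- function(statistic, dof, kind, grid)
  new("StatMap", statistic = statistic, dof = dof, kind = kind, grid = grid)

# ---- show methods -----------------------------------------------------------

setMethod("show", "TaskDesign", function(object) {
  cat(sprintf(
    "TaskDesign: %d run(s) x %d trials (%dC/%dI), stim %.0f ms, ISI %.0f-%.0f ms\n",
    object@nRuns, object@trialsPerRun, object@nCongruentPerRun,
    object@nIncongruentPerRun, object@stimDurationMs, object@isiMinMs,
    object@isiMaxMs))
  cat(sprintf("  TR %.0f ms, %d volumes/run (%.0f s/run, %.0f s total)\n",
              object@trMs, object@volumesPerRun, runDurationS(object),
              taskDurationS(object)))
})

setMethod("show", "AcquisitionGrid", function(object) {
  cat(sprintf("AcquisitionGrid: %s voxels of %s mm, TR %.0f ms\n",
              paste(object@dims, collapse = " x "),
              paste(object@voxelSizeMm, collapse = " x "), object@trMs))
})

setMethod("show", "EffectTemplate", function(object) {
  cat(sprintf("EffectTemplate with %d region(s):\n", nrow(object@regions)))
  print(object@regions)
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d volumes x %d regressors (%d run(s), hpf %.0f s)\n",
              nrow(object@values), ncol(object@values),
              length(unique(object@runIndex)), object@hpfCutoffS))
  if (length(object@absent))
    cat("  absent condition columns:", paste(object@absent, collapse = ", "), "\n")
})

setMethod("show", "GLMFit", function(object) {
  cat(sprintf("GLMFit: %d regressors x %d voxels, dof %.0f\n",
              nrow(object@beta), ncol(object@beta), object@dof))
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap (%s): %s grid, dof %.0f, range [%.2f, %.2f]\n",
              object@kind, paste(dim(object@statistic), collapse = " x "),
              object@dof, min(object@statistic), max(object@statistic)))
})
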