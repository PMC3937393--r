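# Accessor generics. Slot access from user code goes through these.

#' Accessors for task designs, grids, fits and maps
#'
#' @param object A package object (TaskDesign, AcquisitionGrid, DesignMatrix,
#'   GLMFit or StatMap).
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nRuns", function(object) standardGeneric("nRuns"))
#' @rdname accessors
#' @export
setGeneric("trMs", function(object) standardGeneric("trMs"))
#' @rdname accessors
#' @export
setGeneric("volumesPerRun", function(object) standardGeneric("volumesPerRun"))
#' @rdname accessors
#' @export
setGeneric("runDurationS", function(object) standardGeneric("runDurationS"))
#' @rdname accessors
#' @export
setGeneric("taskDurationS", function(object) standardGeneric("taskDurationS"))
#' @rdname accessors
#' @export
setGeneric("gridDims", function(object) standardGeneric("gridDims"))
#' @rdname accessors
#' @export
setGeneric("voxelSizeMm", function(object) standardGeneric("voxelSizeMm"))
#' @rdname accessors
#' @export
setGeneric("affine", function(object) standardGeneric("affine"))
#' @rdname accessors
#' @export
setGeneric("designValues", function(object) standardGeneric("designValues"))
#' @rdname accessors
#' @export
setGeneric("regressorNames", function(object) standardGeneric("regressorNames"))
#' @rdname accessors
#' @export
setGeneric("absentConditions", function(object) standardGeneric("absentConditions"))
#' @rdname accessors
#' @export
setGeneric("residVar", function(object) standardGeneric("residVar"))
#' @rdname accessors
#' @export
setGeneric("dof", function(object) standardGeneric("dof"))
#' @rdname accessors
#' @export
setGeneric("statValues", function(object) standardGeneric("statValues"))
#' @rdname accessors
#' @export
setGeneric("statKind", function(object) standardGeneric("statKind"))
#' @rdname accessors
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))

#' @rdname accessors
#' @export
setMethod("nRuns", "TaskDesign", function(object) object@nRuns)
#' @rdname accessors
#' @export
setMethod("trMs", "TaskDesign", function(object) object@trMs)
#' @rdname accessors
#' @export
setMethod("trMs", "AcquisitionGrid", function(object) object@trMs)
#' @rdname accessors
#' @export
setMethod("volumesPerRun", "TaskDesign", function(object) object@volumesPerRun)
#' @rdname accessors
#' @export
setMethod("runDurationS", "TaskDesign",
          function(object) object@trMs * object@volumesPerRun / 1000)
#' @rdname accessors
#' @export
setMethod("taskDurationS", "TaskDesign",
          function(object) object@nRuns * runDurationS(object))
#' @rdname accessors
#' @export
setMethod("gridDims", "AcquisitionGrid", function(object) object@dims)
#' @rdname accessors
#' @export
setMethod("voxelSizeMm", "AcquisitionGrid", function(object) object@voxelSizeMm)
#' @rdname accessors
#' @export
setMethod("affine", "AcquisitionGrid", function(object) object@affine)
#' @rdname accessors
#' @export
setMethod("designValues", "DesignMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("regressorNames", "DesignMatrix",
          function(object) colnames(object@values))
#' @rdname accessors
#' @export
setMethod("absentConditions", "DesignMatrix", function(object) object@absent)
#' @rdname accessors
#' @param object A GLMFit.
#' @export
setMethod("coef", "GLMFit", function(object) object@beta)
#' @rdname accessors
#' @export
setMethod("residVar", "GLMFit", function(object) object@residVar)
#' @rdname accessors
#' @export
setMethod("dof", "GLMFit", function(object) object@dof)
#' @rdname accessors
#' @export
setMethod("dof", "StatMap", function(object) object@dof)
#' @rdname accessors
#' @export
setMethod("statValues", "StatMap", function(object) object@statistic)
#' @rdname accessors
#' @export
setMethod("statKind", "StatMap", function(object) object@kind)
#' @rdname accessors
#' @export
setMethod("regions", "EffectTemplate", function(object) object@regions)

#' Map voxel indices to MNI millimetres and back
#'
#' @param grid An [AcquisitionGrid-class].
#' @param ijk Matrix (n x 3) of 1-based voxel indices.
#' @param xyz Matrix (n x 3) of MNI mm coordinates.
#' @return An n x 3 matrix of coordinates.
#' @export
voxelToMm <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  t(grid@affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' @rdname voxelToMm
#' @export
mmToVoxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  t(solve(grid@affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}
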