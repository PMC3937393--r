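#' Write and read 4D BOLD volumes as NIfTI-1
#'
#' Thin wrappers around RNifti that carry the grid affine (RAS+, 1-based
#' voxel indices shifted to NIfTI's 0-based convention) and TR.
#'
#' @param bold 3D or 4D numeric array.
#' @param grid The [AcquisitionGrid-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `writeBoldNifti` returns `path` invisibly; `readBoldNifti`
#'   returns a plain numeric array.
#' @export
writeBoldNifti <- function(bold, grid, path) {
  aff <- grid@affine
  # NIfTI voxel indices are 0-based; ours are 1-based
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% rep(1, 3)
  img <- RNifti::asNifti(bold)
  img <- RNifti::`sform<-`(img, structure(aff, code = 4L))
  RNifti::pixdim(img) <- c(grid@voxelSizeMm,
                           if (length(dim(bold)) == 4L) grid@trMs / 1000)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeBoldNifti
#' @export
readBoldNifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Write and read BIDS-style events tables
#'
#' Tab-separated events with columns `onset` and `duration` in seconds plus
#' the trial, behavioral and (when present) condition columns.
#'
#' @param labeled Trial or labeled-trial data.frame.
#' @param design The [TaskDesign-class] (for the stimulus duration).
#' @param path Output `.tsv` path.
#' @return `writeEventsTsv` returns `path` invisibly; `readEventsTsv`
#'   returns a data.frame.
#' @export
writeEventsTsv <- function(labeled, design, path) {
  out <- data.frame(onset = labeled$onset_ms / 1000,
                    duration = design@stimDurationMs / 1000)
  for (col in c("run_index", "trial_index", "direction", "position",
                "congruent", "rt_ms", "correct", "omitted", "rt_outlier",
                "condition"))
    if (col %in% names(labeled)) out[[col]] <- labeled[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsTsv
#' @export
readEventsTsv <- function(path) {
  df <- utils::read.delim(path)
  if (!is.null(df$condition))
    df$condition <- factor(df$condition,
                           levels = c("cC", "cI", "iC", "iI",
                                      "run_initial", "nuisance"))
  df
}

#' Write and read a participants table
#'
#' @param cohort Cohort data.frame from [generateCohort()].
#' @param path Output `.tsv` path.
#' @return `writeParticipantsTsv` returns `path` invisibly.
#' @export
writeParticipantsTsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeParticipantsTsv
#' @export
readParticipantsTsv <- function(path) utils::read.delim(path)
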